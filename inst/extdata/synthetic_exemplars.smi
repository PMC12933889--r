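# Synthetic-compound exemplar set used to train the packaged NP-likeness
# contribution table: flat aromatic/heteroaromatic scaffolds typical of
# synthetic screening compounds and kinase inhibitors.
c1ccc(-c2ccccc2)cc1	biphenyl
Clc1ccc(-c2ccccc2)cc1	chlorobiphenyl
FC(F)(F)c1ccc(Nc2ccccc2)cc1	cf3_diarylamine
O=S(=O)(Nc1ccccc1)c1ccccc1	diaryl_sulfonamide
c1ccc2ncccc2c1	quinoline
c1ccc2[nH]ccc2c1	indole
c1ccc2ncncc2c1	quinazoline_core
Nc1ncnc2ccccc12	aminoquinazoline
c1ccc(-c2ccncc2)cc1	phenylpyridine
c1ccc(Oc2ccccc2)cc1	diphenyl_ether
O=C(Nc1ccccc1)Nc1ccccc1	diphenylurea
c1ccc(Cn2ccnc2)cc1	benzylimidazole
Clc1cccc(Cl)c1-c1ccccc1	dichlorobiphenyl
c1cnc2[nH]ccc2c1	azaindole
c1ccc(-c2nc3ccccc3[nH]2)cc1	phenylbenzimidazole
Nc1ccc(S(N)(=O)=O)cc1	sulfanilamide
O=[N+]([O-])c1ccc(Nc2ccccc2)cc1	nitro_diarylamine
c1ccc(N2CCN(c3ccccc3)CC2)cc1	diphenylpiperazine
Fc1ccc(-c2ccc(F)cc2)cc1	difluorobiphenyl
c1ccc(-c2ccc3ccccc3c2)cc1	phenylnaphthalene
O=C(c1ccccc1)c1ccccc1	benzophenone
c1ccc(SC2=NC=CC=N2)cc1	arylthiopyrimidine
Nc1ncnc(Nc2ccccc2)c1	diaminopyrimidine_aryl
Clc1ccccc1Nc1ncccn1	chloroanilino_pyrimidine
c1ccc(C#Cc2ccccc2)cc1	diphenylacetylene
N#Cc1ccc(-c2ccccc2)cc1	cyanobiphenyl
c1ccc(-n2cccn2)cc1	arylpyrazole
O=C(Nc1ccc(Cl)cc1)c1ccccc1	benzanilide_chloro
c1ccc2c(c1)sc1ccccc12	dibenzothiophene
Brc1ccc(-c2ncccn2)cc1	bromophenyl_pyrimidine
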