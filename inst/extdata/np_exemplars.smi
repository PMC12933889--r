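# Natural-product-like exemplar set used to train the packaged
# NP-likeness contribution table: sugars, terpenoids, polyketide- and
# alkaloid-flavored saturated scaffolds rich in stereocenters and oxygen.
OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O	glucose
OC[C@H]1O[C@](O)(CO)[C@@H](O)[C@@H]1O	fructose
OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1N	glucosamine
OC[C@H](O)[C@@H](O)[C@H](O)[C@H](O)CO	sorbitol
OC1CCC2(C)C(CCC3(C)C2CCC3O)C1	steroid_diol_core
CC1CCC(C(C)C)C(O)C1	menthol_like
CC1(C)C2CCC1(C)C(=O)C2	camphor
CC(=CCCC(C)(O)C=C)C	linalool
CC1=CCC(CC1)C(C)=C	limonene
CC(C)=CCC/C(C)=C/CO	geraniol
OCC1OC(OC2C(O)C(O)C(O)OC2CO)C(O)C(O)C1O	disaccharide
C[C@@H]1CC[C@H]2[C@@H](C)CCC[C@H]2C1	decalin_dimethyl
O=C1OC[C@@H]2CC[C@H](O)C[C@H]12	bicyclic_lactone
C[C@H]1O[C@H](C)C[C@@H](O)C1=O	pyranone_sugar
OC(=O)C1CCC(CC1)C(O)=O	cyclohexane_diacid
N[C@@H](CC1CCCCC1)C(O)=O	cyclohexylalanine
C[C@H](O)[C@@H](N)C(O)=O	threonine
OC(=O)C[C@H](O)C[C@H](O)CC(O)=O	polyol_diacid
CC(C)C[C@@H]1NC(=O)[C@H](C)NC1=O	diketopiperazine
O=C1C[C@@H](C)[C@H](O)[C@@H](C)C1	substituted_cyclohexanone
C[C@@H]1CC[C@@H](O)[C@H](N)C1	aminocyclohexanol
OC[C@H]1NC[C@@H](O)[C@@H](O)[C@@H]1O	iminosugar
CC1(C)CCC[C@]2(C)C1CC[C@@H](O)C2	drimane_fragment
O[C@@H]1C=C[C@H](O)[C@@H](O)C1	cyclohexene_triol
C[C@H]1CCC[C@@H](O)[C@@H]1C	dimethyl_cyclohexanol
O=C1O[C@@H](C)CC=C1C	butenolide
OCC(O)C(O)C(O)CO	pentitol
C[C@@H](O)CC[C@H](C)O	hexanediol
N[C@@H]1CC[C@H](O)CC1	aminocyclohexanol_para
CC(C)[C@@H]1CC[C@H](C)C[C@H]1O	menthol
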