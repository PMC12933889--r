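smiles,n_carbons,fsp3,fc_stereo,nar,hba,hbd,nrb
C,1,1.0000000000,0.0000000000,0,0,0,0
CC,2,1.0000000000,0.0000000000,0,0,0,0
CCC,3,1.0000000000,0.0000000000,0,0,0,0
CCCC,4,1.0000000000,0.0000000000,0,0,0,1
CC(C)C,4,1.0000000000,0.0000000000,0,0,0,0
CCCCC,5,1.0000000000,0.0000000000,0,0,0,2
CC(C)(C)C,5,1.0000000000,0.0000000000,0,0,0,0
CCO,2,1.0000000000,0.0000000000,0,1,1,0
CCN,2,1.0000000000,0.0000000000,0,1,1,0
CCOC,3,1.0000000000,0.0000000000,0,1,0,1
CC(=O)O,2,0.5000000000,0.0000000000,0,2,1,0
CC(=O)N,2,0.5000000000,0.0000000000,0,2,1,0
CC(=O)OC,3,0.6666666667,0.0000000000,0,2,0,1
CCC(=O)O,3,0.6666666667,0.0000000000,0,2,1,1
CC(N)C(=O)O,3,0.6666666667,0.3333333333,0,3,2,1
C[C@H](N)C(=O)O,3,0.6666666667,0.3333333333,0,3,2,1
OCC(O)CO,3,1.0000000000,0.0000000000,0,3,3,2
NCCO,2,1.0000000000,0.0000000000,0,2,2,1
CC(C)O,3,1.0000000000,0.0000000000,0,1,1,0
CC(C)N,3,1.0000000000,0.0000000000,0,1,1,0
c1ccccc1,6,0.0000000000,0.0000000000,1,0,0,0
Cc1ccccc1,7,0.1428571429,0.0000000000,1,0,0,0
CCc1ccccc1,8,0.2500000000,0.0000000000,1,0,0,1
Oc1ccccc1,6,0.0000000000,0.0000000000,1,1,1,0
Nc1ccccc1,6,0.0000000000,0.0000000000,1,1,1,0
COc1ccccc1,7,0.1428571429,0.0000000000,1,1,0,1
Clc1ccccc1,6,0.0000000000,0.0000000000,1,0,0,0
c1ccncc1,5,0.0000000000,0.0000000000,1,1,0,0
c1cc[nH]c1,4,0.0000000000,0.0000000000,1,1,1,0
c1ccoc1,4,0.0000000000,0.0000000000,1,1,0,0
c1ccsc1,4,0.0000000000,0.0000000000,1,0,0,0
c1ccc2ccccc2c1,10,0.0000000000,0.0000000000,2,0,0,0
c1ccc2ncccc2c1,9,0.0000000000,0.0000000000,2,1,0,0
Cc1ccncc1,6,0.1666666667,0.0000000000,1,1,0,0
Oc1ccncc1,5,0.0000000000,0.0000000000,1,2,1,0
c1ccc(-c2ccccc2)cc1,12,0.0000000000,0.0000000000,2,0,0,1
C1CCCCC1,6,1.0000000000,0.0000000000,0,0,0,0
C1CCCC1,5,1.0000000000,0.0000000000,0,0,0,0
C1CCNCC1,5,1.0000000000,0.0000000000,0,1,1,0
C1CCOCC1,5,1.0000000000,0.0000000000,0,1,0,0
CC1CCCCC1,7,1.0000000000,0.0000000000,0,0,0,0
OC1CCCCC1,6,1.0000000000,0.0000000000,0,1,1,0
O=C1CCCCC1,6,0.8333333333,0.0000000000,0,1,0,0
C1CCC=CC1,6,0.6666666667,0.0000000000,0,0,0,0
C1CC2CCC1C2,7,1.0000000000,0.0000000000,0,0,0,0
CC1CCCO1,5,1.0000000000,0.2000000000,0,1,0,0
C1COCCN1,4,1.0000000000,0.0000000000,0,2,1,0
CC(=O)c1ccccc1,8,0.1250000000,0.0000000000,1,1,0,1
OC(=O)c1ccccc1O,7,0.0000000000,0.0000000000,1,3,2,1
CC#N,2,0.5000000000,0.0000000000,0,1,0,0
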