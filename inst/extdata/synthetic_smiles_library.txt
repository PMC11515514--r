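COc4ccncc4c5ccsc5c6ccsc6
CCC(OC)C(C#N)N
OOC(Br)c5ccncc5O
Cc3ccsc3c4ccsc4OC
C2CCOC2O
C2CCNCC2Oc4ccncc4Cc6ccsc6
OO
CONNc6ccsc6
Cc3ccncc3
C2CCCCC2c3ccsc3C(O)
C2CCCC2c3ccncc3N
OS
C2CCCC2Sc4ccsc4
C2CCOC2CCC
C(Br)NS
OC3CCNCC3C
c2ccncc2C3CCOC3c4cc[nH]c4c5cc[nH]c5
C2CCCCC2c3cc[nH]c3C4CCCC4C(N)
CO
C2CCCC2CCC5CCCCC5
C(C)C3CCNCC3C(C#N)
c2cc[nH]c2C
SCS
CC(Br)
C2CCCCC2C
c2cc[nH]c2C(F)
C2CCCCC2C3CCCCC3C4CCOC4c5cc[nH]c5c6ccsc6
c2ccccc2CSC
CC(O)C4CCOC4c5ccccc5
C(C#N)CNc5ccncc5C(O)
NCc4ccncc4
c2cc[nH]c2S
CS
C2CCCC2NSC
CSNSc6ccccc6
C2CCNCC2c3cc[nH]c3c4ccsc4C(F)O
C2CCOC2N
C(N)NS
OC3CCNCC3
Cc3ccncc3OC
C2CCCCC2c3cc[nH]c3C(C#N)c5cc[nH]c5
C2CCOC2c3ccsc3Cc5ccncc5
Oc3ccccc3
NC(Br)c4ccccc4
NC
c2cc[nH]c2C3CCOC3COC6CCNCC6
ONC
c2ccsc2SCOC
C(C(=O)O)C(O)C
c2ccncc2N
NC3CCOC3CC5CCNCC5
c2ccncc2c3ccsc3C4CCCC4C5CCOC5
C2CCNCC2C(Cl)C4CCCC4NC(F)
CNC4CCOC4
C2CCCC2c3ccncc3
c2ccccc2OC(F)
C2CCCC2Cc4cc[nH]c4
OC(F)CS
C(F)c3cc[nH]c3C4CCCC4
OSC4CCCC4C(N)
Nc3ccccc3C4CCNCC4C5CCCCC5
C2CCCCC2SCSC(OC)
C(C)CNCS
CC
C(C(=O)O)C3CCOC3C(OC)N
c2ccccc2C3CCNCC3N
NCOc5ccccc5O
c2ccccc2CSC5CCNCC5
CC3CCNCC3c4ccncc4c5cc[nH]c5
C2CCNCC2CC(C(=O)N)C(C#N)c6ccsc6
OOCNC6CCNCC6
NCC(OC)SO
C2CCCC2CC4CCCC4C5CCCC5C
Oc3ccsc3c4ccncc4c5ccncc5C6CCCCC6
c2cc[nH]c2CCc5cc[nH]c5N
c2ccncc2ON
NCNSC6CCCCC6
C2CCNCC2c3ccccc3S
C2CCNCC2NSOc6cc[nH]c6
NOC4CCCC4
OC(O)SC5CCCC5C(C(=O)N)
OSC
C(C(=O)N)C(OC)
C(O)C3CCNCC3COc6cc[nH]c6
c2ccncc2C(N)c4ccccc4
C2CCOC2c3ccncc3c4ccccc4c5ccncc5
CC3CCNCC3c4ccsc4C5CCCCC5
NC3CCOC3Sc5ccsc5C6CCCCC6
OC(F)S
C(N)OC4CCOC4
c2cc[nH]c2C(F)C4CCNCC4
OCc4ccncc4C5CCCCC5N
SSc4ccncc4c5ccsc5
C2CCCCC2Oc4ccncc4
C2CCCC2SC4CCNCC4
Cc3cc[nH]c3C(C(=O)O)C5CCCCC5
NSNSO
c2ccsc2CC4CCOC4
Sc3cc[nH]c3
c2ccccc2C3CCOC3CNc6cc[nH]c6
ONCC
C(C(=O)N)C3CCCCC3NC(Cl)
C2CCNCC2NC(OC)C5CCNCC5C
C(O)SC4CCOC4c5cc[nH]c5C6CCCCC6
Cc3cc[nH]c3Cc5ccccc5
c2ccsc2SN
c2ccsc2SC(F)
C(C(=O)O)C3CCOC3O
C(C#N)OC4CCCC4C5CCCC5c6ccccc6
C2CCCCC2N
C2CCCCC2SO
Cc3ccncc3C4CCCC4
NC3CCCC3
CC3CCCCC3C
OC(C(=O)N)
C2CCCC2NC
C(Cl)C(Cl)
c2ccncc2C(F)
SCC4CCNCC4OC(C(=O)O)
CC3CCCC3O
CNC(Br)
NOSc5ccncc5
C2CCOC2c3cc[nH]c3ON
c2ccsc2CNC5CCNCC5N
OCSOO
SC
OC(C#N)c4cc[nH]c4
C(C#N)Oc4ccsc4
C(N)OS
SC3CCOC3C(Cl)C(C(=O)N)C6CCNCC6
C(OC)C3CCOC3c4ccncc4c5ccsc5
CC(OC)
C2CCCCC2C3CCOC3C4CCNCC4N
C(F)S
c2ccsc2O
C2CCCC2C3CCCCC3C(Cl)N
c2ccsc2C(C(=O)N)C
C(C)NNS
OCCO
NO
c2ccncc2C(OC)N
C2CCNCC2OC4CCCC4
C2CCOC2CC4CCCC4c5ccccc5c6ccncc6
C2CCCCC2O
c2ccccc2C3CCOC3S
CNN
C(Cl)Cc4ccncc4C
OC(O)C(F)
Nc3ccccc3
Sc3ccncc3S
C(C)C(C(=O)N)c4ccccc4C5CCNCC5
CCC4CCNCC4C
SC(O)C(C(=O)O)CC
Oc3cc[nH]c3C(O)SS
OC(Br)SC
C(OC)SC(OC)SC6CCCC6
ON
Nc3ccncc3Cc5ccsc5
C(C#N)C
C(C(=O)O)CCOC6CCCC6
NC3CCCCC3
Nc3ccncc3NCC6CCCC6
CNOC(Br)c6ccncc6
C(C(=O)O)C(N)
C2CCNCC2C(C(=O)N)c4ccccc4
NC(O)C4CCNCC4C(N)
C2CCNCC2c3cc[nH]c3
OC3CCNCC3C4CCCC4SO
c2ccccc2O
c2ccsc2CCNC6CCCC6
c2ccccc2Cc4ccsc4
CN
C2CCNCC2CC4CCCCC4NC
C(Cl)C3CCOC3Oc5ccncc5
CSc4ccsc4CC
c2cc[nH]c2OOCO
c2ccncc2Sc4ccsc4
CC(N)
SC(O)C(N)C(F)S
C(C#N)c3ccncc3C
C2CCNCC2c3ccncc3S
C2CCOC2SC4CCNCC4C
c2ccccc2S
C2CCCC2C(C(=O)N)Nc5cc[nH]c5S
c2ccncc2CC(N)C5CCCC5C(C)
C(Br)C
C(OC)c3ccccc3
OSNCC6CCNCC6
C(Br)Nc4ccsc4c5cc[nH]c5
C2CCOC2COc5cc[nH]c5C
COC
c2cc[nH]c2CSC
SCC4CCOC4c5ccccc5c6cc[nH]c6
CSN
c2ccsc2CSC5CCOC5O
COCC5CCNCC5C(N)
OC3CCCC3C(N)C5CCNCC5
COC4CCNCC4
CSSN
C(OC)c3ccccc3C
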