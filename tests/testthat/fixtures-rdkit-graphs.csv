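smiles,n_atoms,n_bonds,n_aromatic,check_aromatic
C,1,0,0,1
CC,2,1,0,1
CCO,3,2,0,1
OCC,3,2,0,1
c1ccccc1,6,6,6,1
CC(O)CO,5,4,0,1
CCN,3,2,0,1
C(=O)O,3,2,0,1
CC(=O)NC,5,4,0,1
c1ccc(O)cc1,7,7,6,1
CC(C)C,4,3,0,1
CCCC,4,3,0,1
C1CCCCC1,6,6,0,1
c1ccncc1,6,6,6,1
CC(=O)Oc1ccccc1C(=O)O,13,13,6,1
CN1C=NC2=C1C(=O)N(C)C(=O)N2C,14,15,9,0
C(=O)NC,4,3,0,1
CCOC(=O)C,6,5,0,1
CSC,3,2,0,1
CS(=O)(=O)C,5,4,0,1
NC(=O)C,4,3,0,1
CC#N,3,2,0,1
C#C,2,1,0,1
CC=C,3,2,0,1
C=O,2,1,0,1
OC=O,3,2,0,1
c1ccsc1,5,5,5,1
c1cc[nH]c1,5,5,5,1
C1CC1,3,3,0,1
C1CCC1,4,4,0,1
CNC,3,2,0,1
CON,3,2,0,1
CCCl,3,2,0,1
CCBr,3,2,0,1
CCI,3,2,0,1
CCF,3,2,0,1
C(F)(F)F,4,3,0,1
[O-]C(=O)C,4,3,0,1
CC[NH3+],3,2,0,1
C[C@H](N)C(=O)O,6,5,0,1
N#Cc1ccccc1,8,8,6,1
Cc1ccccc1,7,7,6,1
Oc1ccccc1,7,7,6,1
Nc1ccccc1,7,7,6,1
ClC(Cl)Cl,4,3,0,1
CC(=O)C,4,3,0,1
CCOCC,5,4,0,1
OCCO,4,3,0,1
NCCN,4,3,0,1
SCC,3,2,0,1
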