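smiles	cleaved_bonds
CC(=O)Nc1ccc(O)cc1	1-3;3-4
CC(C)Cc1ccc(cc1)C(C)C(=O)O	3-4;7-10
c1ccc2c(c1)cccc2	
CN1CCC(CC1)Oc1ccccc1	4-7;7-8
CCOC(=O)c1ccccc1N	1-2;2-3;3-5
CC(=O)OCC	1-3;3-4
CCOCC	1-2;2-3
CCSCC	1-2;2-3
CS(=O)(=O)c1ccccc1	
O=C1CCCCN1C	
c1ccncc1CC	5-6
c1ccoc1CNC(C)=O	4-5;5-6;6-7
CC(C)(C)OC(=O)NC1CCNCC1	1-4;4-5;5-7;7-8
CCN(CC)CCNC(=O)c1ccc(N)cc1	1-2;2-3;2-5;6-7;7-8;8-10
Clc1ccccc1Br	
OCC1OC(O)C(O)C(O)C1O	1-2
CC1=CC(=O)CC(C)(C)C1	
N#Cc1ccccc1OC	7-8
C=CCOc1ccccc1	2-3;3-4
CCC(=O)N(C)C	2-4
CN(C)CCOC(c1ccccc1)c1ccccc1	1-3;4-5;5-6;6-7;6-13
CC(N)C(=O)O	
c1cnc2[nH]ccc2c1	
CC(C)NCC(O)COc1ccccc1	1-3;3-4;7-8;8-9
FC(F)(F)c1ccccc1NC(=O)C	1-4;9-10;10-11
CCOP(=O)(OCC)OCC	1-2;5-6;8-9
CC1CCC(CC1)NC	4-7
c1csc(c1)C(=O)N	3-5
CC(=O)N1CCCC1	1-3
Cc1nccn1C	
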