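index,name,smiles
0,4CzIPN,N#Cc1c(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)c(C#N)c(-n2c3ccccc3c3ccccc32)c1-n1c2ccccc2c2ccccc21
1,Ir1,[Ir+3].[c-]1ccccc1-c1ccccn1.[c-]1ccccc1-c1ccccn1.[c-]1ccccc1-c1ccccn1
2,Ir2,[Ir+3].[c-]1ccccc1-c1ccccn1.[c-]1ccccc1-c1ccccn1.CC(C)(C)c1ccnc(-c2cc(ccn2)C(C)(C)C)c1
3,Ir3,[Ir+3].[c-]1cc(F)cc(F)c1-c1cc(ccn1)C(F)(F)F.[c-]1cc(F)cc(F)c1-c1cc(ccn1)C(F)(F)F.CC(C)(C)c1ccnc(-c2cc(ccn2)C(C)(C)C)c1
4,Ir4,[Ir+3].[c-]1cc(F)cc(F)c1-c1ccccn1.[c-]1cc(F)cc(F)c1-c1ccccn1.[c-]1cc(F)cc(F)c1-c1ccccn1
5,Ru1,[Ru+2].c1ccc(-c2ccccn2)nc1.c1ccc(-c2ccccn2)nc1.c1ccc(-c2ccccn2)nc1
6,Ru2,[Ru+2].c1ccc2ccc3cccnc3c2n1.c1ccc2ccc3cccnc3c2n1.c1ccc2ccc3cccnc3c2n1
7,Cu1,[Cu+].COc1ccc(cc1)-c1ccc2ccc3ccc(nc3c2n1)-c1ccc(OC)cc1.COc1ccc(cc1)-c1ccc2ccc3ccc(nc3c2n1)-c1ccc(OC)cc1
8,EY,[O-]c1c(Br)cc2c(c1Br)Oc1c(Br)c([O-])c(Br)cc1C2=C1C=CC=CC1C(=O)O
9,RhB,CCN(CC)c1ccc2c(c1)Oc1cc(ccc1C2=C1C=CC=CC1C(=O)O)N(CC)CC
10,RoB,[O-]c1c(I)cc2c(c1I)Oc1c(I)c([O-])c(I)cc1C2=C1C(Cl)=C(Cl)C(Cl)=C(Cl)C1C(=O)O
11,ClA,O=C1C(Cl)=C(Cl)C(=O)C(Cl)=C1Cl
12,TPPT,c1ccc(cc1)-c1cc(-c2ccccc2)[o+]c(-c2ccccc2)c1
13,AnQ,O=C1c2ccccc2C(=O)c2ccccc21
14,PTH,c1ccc(cc1)N1c2ccccc2Sc2ccccc21
15,FlS,[O-]c1ccc2c(c1)Oc1cc([O-])ccc1C2=C1C=CC=CC1C(=O)O
16,BP,O=C(c1ccccc1)c1ccccc1
17,XO,O=C1c2ccccc2Oc2ccccc21
18,TXO,O=C1c2ccccc2Sc2ccccc21
19,FO,O=C1c2ccccc2-c2ccccc21
20,MesAcr,Cc1cc(C)c(-c2c3ccccc3[n+](C)c3ccccc23)c(C)c1
21,MB,CN(C)c1ccc2nc3ccc(cc3[s+]c2c1)N(C)C
22,Rh6G,CCNc1cc2c(cc1C)C1=C(C=CC=C1C(=O)OCC)C1=[O+]C2=CC(C)=C1NCC
23,RF,Cc1cc2nc3c(=O)[nH]c(=O)n(CC(O)C(O)C(O)CO)c3nc2cc1C
24,Per,c1cc2cccc3c2c2c1cccc2c1cccc(c1)c3
25,DDQ,N#CC1=C(C#N)C(=O)C(Cl)=C(Cl)C1=O
26,Benzil,O=C(C(=O)c1ccccc1)c1ccccc1
27,SfO,Cc1cc2nc3cc(C)c(N)cc3[n+](-c3ccccc3)c2cc1N
28,DCA,N#Cc1c2ccccc2c(C#N)c2ccccc21
29,ClAnQ,O=C1c2ccccc2C(=O)c2cc(Cl)ccc21
30,Pyr,c1cc2ccc3cccc4ccc(c1)c2c34
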