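band_nm,label,lo_nm,hi_nm,importance,assignment
1348,C1,1336,1348,2,antisymmetric OH stretch of water (nu3)
1360,C2,1360,1366,3,water solvation shell OH-(H2O)1/2/4; water vapor; proton hydrates
1373,C3,1370,1376,3,combination of symmetric and asymmetric OH stretch (nu1+nu3); water vapor; proton hydrates
1379,C4,1380,1388,4,water solvation shell OH-(H2O)1/4; superoxide hydrate; water vapor; proton hydrates
1385,C4,1380,1388,4,water solvation shell OH-(H2O)1/4; superoxide hydrate; water vapor; proton hydrates
1391,C5,1396,1403,4,confined single water molecules (trapped water); free OH trapped in hydrophobic interior
1397,C5,1396,1403,4,confined single water molecules (trapped water); free OH trapped in hydrophobic interior
1404,C5,1404,1414,2,free water molecules
1410,C5,1404,1414,3,free water molecules
1416,C5,1404,1414,1,free water molecules
1428,C6,1421,1430,3,water hydration band; H-OH bend; first overtone of fundamental OH stretch
1435,C7,1432,1444,1,non-bonded O-H stretching first overtone; OH bending overtone of water dimer
1441,C7,1432,1444,1,non-bonded O-H stretching first overtone; OH bending overtone of water dimer
1447,C8,1448,1454,5,water solvation shell OH-(H2O)4/5
1453,C8,1448,1454,1,water solvation shell OH-(H2O)4/5
1459,C9,1458,1468,3,water molecules with two hydrogen bonds
1466,C9,1458,1468,1,water molecules with two hydrogen bonds
1472,C10,1472,1482,1,water molecules with three hydrogen bonds
1478,C10,1472,1482,4,water molecules with three hydrogen bonds
1484,C11,1482,1495,2,water molecules with four hydrogen bonds
1490,C11,1482,1495,2,water molecules with four hydrogen bonds
1497,C11,1482,1495,2,water molecules with four hydrogen bonds
1503,Ci,1503,1503,4,strongly bound water; intermolecular hydrogen bonds; OH stretch in ice III
1509,C12,1506,1516,1,strongly bound water; symmetric stretch and bending fundamentals (nu1 nu2)
1521,C12,1506,1516,1,strongly bound water; symmetric stretch and bending fundamentals (nu1 nu2)
1528,Cj,1528,1528,4,strongly bound water; intermolecular hydrogen bonds
1534,Ck,1534,1534,5,hydrogen bonded hydroxyl groups; bound O-H stretching first overtone; bending fundamental
1559,Cl,1559,1559,4,ionic bound water first overtone; strongly hydrogen bonded water; crystalline water ice
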