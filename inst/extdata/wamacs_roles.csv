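band_nm,roles
1348,self-organization; germination; changes during storage; viability
1360,germination; water activity and changes during storage; hardness; viability; texture
1373,water vapor band; proton hydration; sucrose content indicator; viability; water activity; texture
1385,hydration of ions; pH modelling; firmness and texture
1391,drying; dehydration; expulsion of cellular water; damage; stress; infection; vitamin C content
1410,moisture content; water activity; seed viability; firmness; vitamin C content
1428,protein hydration and folding; water activity; damage and defects
1435,phase transition; carbohydrate-water interaction; hardness; viability
1441,preservation during desiccation stress
1447,water activity; biotic and abiotic stress indicator; preservation; damage
1459,water activity; biotic and abiotic stress indicator; preservation; damage
1466,protein-water interaction
1478,semi-crystalline water associated with cellulose or other polymers; stiffness
1484,associated with cellulose or other polymers; tissue preservation; damage
1490,water activity; biotic and abiotic stress indicator; preservation; damage
1503,skin disease in plants and animals; defects in minerals; structural defects in starch
1521,structural water; water-polymer interaction; fresh/thawed discrimination; mechanical damage
1528,structural water; water-polymer interaction; fresh/thawed discrimination; mechanical damage
1534,structural water; water-cellulose interaction; drying indicator; water sorption and clustering
1559,structural water; polymers and sugars; membrane structure; crystallinity; tissue preservation
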