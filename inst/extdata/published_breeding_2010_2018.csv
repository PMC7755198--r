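region,unit,country,subnational,breeding_individuals,n_years
North America,US-East and West Coast,USA,New York,21,2
North America,US-Gulf of Mexico/Florida,USA,Florida,1930,9
North America,Mexico-Central,Mexico,Jalisco,10,2
North America,Mexico-Yucatan Peninsula,Mexico,Yucatán,117916,9
South America,Bonaire,Bonaire,,21428,9
South America,Colombia,Colombia,,17900,9
South America,Curaçao,Curaçao,,11764,8
South America,Ecuador,Ecuador,,3610,9
South America,Guyana,Guyana,,40,1
South America,Suriname,Suriname,,295,3
South America,Venezuela,Venezuela,,243369,9
Caribbean,Anguilla,Anguilla,,7,1
Caribbean,Aruba,Aruba,,142,6
Caribbean,Bahamas,Bahamas,,11463,6
Caribbean,Barbados,Barbados,,4,1
Caribbean,Cayman Island,Cayman Island,,9,2
Caribbean,Cuba,Cuba,,85007,8
Caribbean,Dominican Republic,Dominican Republic,,553,9
Caribbean,Granada,Granada,,1,1
Caribbean,Haiti,Haiti,,435,3
Caribbean,Jamaica,Jamaica,,1,1
Caribbean,Puerto Rico,Puerto Rico,,172,9
Caribbean,Saint Martin,Saint Martin,,4,1
Caribbean,Trinidad and Tobago,Trinidad and Tobago,,1726,6
Caribbean,Turks and Caicos Islands,Turks and Caicos Islands,,9688,8
Caribbean,Virgin Island,Virgin Island,,1269,7
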