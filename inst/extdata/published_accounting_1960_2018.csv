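region,country,n_record,n_duplicate,n_qualitative,n_final,cum_individuals,first_record_year
North America,Bermuda,51,0,2,49,65,1969
North America,Canada,2,0,0,2,81,1978
North America,USA,1269,580,33,656,3939,1971
North America,Mexico,3678,1275,301,2102,570953,1980
Central America,Belize,1,0,0,1,1,2007
Central America,Honduras,1,0,0,1,1,2011
South America,Bonaire,2370,1307,100,963,109249,1984
South America,Brazil,1,0,0,1,150,2005
South America,Colombia,661,202,54,405,51519,1979
South America,Curaçao,1152,413,20,719,37459,1992
South America,Ecuador,1772,370,387,1015,9771,1973
South America,Guyana,7,2,0,5,76,2013
South America,Suriname,37,13,6,18,5105,2011
South America,Venezuela,714,253,132,329,1036458,1982
Caribbean,Anguilla,13,4,0,9,13,2015
Caribbean,Aruba,111,17,0,94,152,1986
Caribbean,Bahamas,406,166,18,222,67700,1976
Caribbean,Barbados,29,10,0,19,19,2004
Caribbean,Cayman Island,91,32,1,58,291,2009
Caribbean,Cuba,2439,1109,197,1133,300560,1985
Caribbean,Dominican Republic,440,102,37,301,9681,1981
Caribbean,Granada,1,0,0,1,1,2017
Caribbean,Guadalupe,1,0,0,1,1,2013
Caribbean,Haiti,60,23,2,35,1239,1987
Caribbean,Jamaica,6,1,0,5,7,2016
Caribbean,Puerto Rico,912,307,8,597,653,1987
Caribbean,Saint Kitts,1,0,0,1,1,2002
Caribbean,Saint Martin,4,0,0,4,7,2014
Caribbean,Trinidad and Tobago,110,22,3,85,2279,2005
Caribbean,Turks and Caicos Islands,440,94,13,333,29773,1976
Caribbean,Virgin Island,150,22,9,119,3176,1979
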