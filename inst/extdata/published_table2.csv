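state,premature_deaths_musd,morbidity_musd,total_musd,per_capita_usd
Bihar,1257,296,1553,12.7
Uttar Pradesh,4255,876,5130,21.1
Manipur,30,11,40,11.5
Jharkhand,408,136,543,14.3
Madhya Pradesh,1614,356,1970,22.2
Assam,528,129,657,18.2
Meghalaya,30,9,39,11.5
Jammu & Kashmir and Ladakh,201,51,252,18.0
Chhattisgarh,549,141,690,21.8
West Bengal,1607,519,2125,21.3
Nagaland,26,8,34,17.2
Odisha,609,197,807,17.3
Rajasthan,1902,392,2294,28.5
Tripura,70,21,91,22.6
Arunachal Pradesh,19,7,26,15.1
Mizoram,17,6,22,17.6
Andhra Pradesh,1007,342,1349,24.9
Punjab,920,229,1149,37.0
Tamil Nadu,1886,643,2529,31.7
Maharashtra,3003,972,3975,31.9
Telangana,841,275,1116,28.7
Kerala,741,349,1091,31.2
Himachal Pradesh,192,62,254,33.3
Karnataka,2113,568,2681,39.4
Uttarakhand,413,114,527,44.5
Gujarat,2288,571,2860,41.3
Haryana,1224,342,1566,53.8
Other small union territories,86,35,120,31.7
Sikkim,17,8,25,38.6
Delhi,893,314,1207,62.0
Goa,54,26,80,52.2
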