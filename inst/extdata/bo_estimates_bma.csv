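section,persons,area_km2,density,density_hat,pop_hat,re_pct
Moibawo Farm,135,0.5,270,206.13,103,-24
Roma,139,0.04,3475,3818.48,153,10
Bo Central,273,0.066,4136.36,3753.27,248,-9
Toubu,454,0.016,28375,27852.13,446,-2
Salina,580,0.467,1241.97,1164.25,544,-6
Dodo,597,0.049,12183.67,12234.85,600,0
Reservation,637,2.329,273.51,282.25,657,3
Kpetewoma,640,0.197,3248.73,2918.91,575,-10
Lewabu,879,0.479,1835.07,2100.07,1006,14
Tengbewabu,1068,0.68,1570.59,1770.75,1204,13
New York,1088,1.513,719.1,585.41,886,-19
Komende,1103,0.196,5627.55,5780.18,1133,3
Kindia Town,1160,0.146,7945.21,8806.61,1286,11
New Site,1248,0.686,1819.24,2061.33,1414,13
Yemoh Town,1858,0.404,4599.01,5379.96,2174,17
Njai Town,2298,0.216,10638.89,10524.21,2273,-1
Kissi Town,2490,0.196,12704.08,12479.6,2446,-2
Nduvuibu,2552,0.493,5176.47,4803.58,2368,-7
New London,2873,0.597,4812.4,4487.98,2679,-7
Kulanda Town,3882,0.294,13204.08,12452.93,3661,-6
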