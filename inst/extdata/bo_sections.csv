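section,persons,area_km2,density
Moibawo Farm,135,0.5,270
Roma,139,0.04,3475
Bo Central,273,0.066,4136.36
Toubu,454,0.016,28375
Salina,580,0.467,1241.97
Dodo,597,0.049,12183.67
Reservation,637,2.329,273.51
Kpetewoma,640,0.197,3248.73
Lewabu,879,0.479,1835.07
Tengbewabu,1068,0.68,1570.59
New York,1088,1.513,719.1
Komende,1103,0.196,5627.55
Kindia Town,1160,0.146,7945.21
New Site,1248,0.686,1819.24
Yemoh Town,1858,0.404,4599.01
Njai Town,2298,0.216,10638.89
Kissi Town,2490,0.196,12704.08
Nduvuibu,2552,0.493,5176.47
New London,2873,0.597,4812.4
Kulanda Town,3882,0.294,13204.08
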