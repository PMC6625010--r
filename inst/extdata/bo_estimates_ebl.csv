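section,persons,area_km2,density,density_hat,pop_hat,re_pct
Moibawo Farm,135,0.5,270.04,203.5,101.75,-24.64
Roma,139,0.04,3510.72,3353.39,134.1356,-4.48
Bo Central,273,0.066,4137.9,4224.7,278.8302,2.10
Toubu,454,0.016,28089.66,27109.01,433.7442,-3.49
Salina,580,0.467,1242.8,1537.59,718.0545,23.72
Dodo,597,0.049,12126.22,12417.3,608.4477,2.40
Reservation,637,2.329,273.51,188,437.852,-31.26
Kpetewoma,640,0.197,3250.74,3374.54,664.7844,3.81
Lewabu,879,0.479,1836.16,2057.56,985.5712,12.06
Tengbewabu,1068,0.68,1571.17,1557.68,1059.222,-0.86
New York,1088,1.513,719.3,604.88,915.1834,-15.91
Komende,1103,0.196,5622.16,5924.81,1161.263,5.38
Kindia Town,1160,0.146,7972.46,8357.53,1220.199,4.83
New Site,1248,0.686,1818.17,1815.95,1245.742,-0.12
Yemoh Town,1858,0.404,4602.47,4455.86,1800.167,-3.19
Njai Town,2298,0.216,10641.33,10061.91,2173.373,-5.44
Kissi Town,2490,0.196,12709.81,12463.32,2442.811,-1.94
Nduvuibu,2552,0.493,5177.21,5661.29,2791.016,9.35
New London,2873,0.597,4813.01,4308.02,2571.888,-10.49
Kulanda Town,3882,0.294,13216.15,13149.33,3865.903,-0.51
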