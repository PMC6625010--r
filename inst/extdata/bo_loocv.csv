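section,persons,area_km2,density,sqrt_d,pred_sqrt_d,d_hat,er_sqrt,pct_er_sqrt,er_d,pct_re_d
Roma,139,0.04,3510.72,59.25,70.39,4954.9,11.14,18.81,1444.18,41.14
Bo Central,273,0.066,4137.9,64.33,60.44,3653.53,3.88,6.03,484.37,-11.71
Toubu,454,0.016,28089.66,167.61,160.05,25617.12,7.55,4.5,2472.54,-8.80
Salina,580,0.467,1242.8,35.25,33.94,1151.93,1.31,3.73,90.87,-7.31
Dodo,597,0.049,12126.22,110.12,111.22,12370.87,1.1,1,244.65,2.02
Reservation,637,2.329,273.51,16.54,16.91,285.8,0.37,2.22,12.3,4.50
Kpetewoma,640,0.197,3250.74,57.02,52.63,2769.82,4.39,7.69,480.92,-14.79
Lewabu,879,0.479,1836.16,42.85,46.54,2166.06,3.69,8.61,329.9,17.97
Tengbewabu,1068,0.68,1571.17,39.64,42.41,1798.53,2.77,6.99,227.36,14.47
New York,1088,1.513,719.3,26.82,23.01,529.41,3.81,14.21,189.89,-26.40
Komende,1103,0.196,5622.16,74.98,76.52,5856.04,1.54,2.06,233.88,4.16
Kindia Town,1160,0.146,7972.46,89.29,94.36,8903.89,5.07,5.68,931.43,11.68
New Site,1248,0.686,1818.17,42.64,47.27,2234.43,4.63,10.86,416.26,22.89
Yemoh Town,1858,0.404,4602.47,67.84,75.01,5626.04,7.17,10.56,1023.57,22.24
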