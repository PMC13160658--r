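mountain,latitude,longitude,tsi,psi,csi_printed,p_temp_printed_pct,p_precip_printed_pct,region,moisture
Carpathians,46.1,24.0,3.955,2.561,6.516,60.70,39.30,europe,humid
Alps,46.2,10.6,1.967,1.389,3.356,58.62,41.38,europe,humid
Crimean,44.6,34.2,1.662,1.016,2.678,52.05,37.95,europe,humid
Dinarides,43.6,18.2,3.453,2.031,5.483,62.97,37.03,europe,humid
Changbai,42.8,127.2,5.857,5.303,11.161,52.48,47.52,east_asia,humid
Caucasus,42.7,42.9,3.891,3.713,7.604,51.17,48.83,other,humid
Balkan,42.7,24.2,4.381,4.243,8.625,50.80,49.20,europe,humid
Apennine,42.3,13.1,5.764,7.763,13.527,42.61,57.39,europe,humid
Rila-Rhodope,41.8,23.0,3.798,11.484,15.282,24.85,75.15,europe,humid
Pindus,40.7,20.4,2.466,4.379,6.845,36.02,63.98,europe,humid
Yanshan,40.3,116.7,4.637,8.843,13.480,34.40,65.60,east_asia,arid_semiarid
Appalachia,39.7,-78.16,2.441,5.475,7.916,30.84,69.16,other,humid
Southern Rocky,39.0,-105.8,4.107,4.498,8.605,47.73,52.27,other,arid_semiarid
Lvliang,37.9,111.5,3.157,6.197,9.354,33.75,66.25,east_asia,arid_semiarid
Taihang,37.8,113.8,3.669,6.817,10.487,34.99,65.01,east_asia,arid_semiarid
Taebaek,37.7,128.6,5.153,3.536,8.689,59.31,40.69,east_asia,humid
Alborz,37.1,50.6,2.395,1.763,4.158,57.60,42.40,other,arid_semiarid
Japanese Alps,36.2,138.0,1.561,3.437,4.998,31.24,68.76,east_asia,humid
Qingling,33.7,108.8,8.178,6.971,15.150,53.98,46.02,east_asia,humid
Daba,31.9,108.8,10.603,4.618,15.221,69.66,30.34,east_asia,humid
Dabie,31.4,115.9,3.766,1.979,5.744,65.56,34.44,east_asia,humid
Cantabrian,43.1,-4.0,2.473,1.394,3.867,63.95,36.05,europe,humid
Pyrenees,42.8,-0.2,3.169,3.350,6.519,48.61,51.39,europe,humid
Himalayas,29.0,83.0,3.110,2.767,5.877,52.92,47.08,other,humid
Middle Hengduan,27.6,99.6,3.702,2.805,6.507,56.90,43.10,other,humid
Sistema Iberico,42.1,-2.8,9.640,2.692,12.332,78.17,21.83,europe,humid
Wuling,29.4,109.2,3.257,9.426,12.683,25.68,74.32,east_asia,humid
Xuefeng,26.7,110.7,1.237,0.797,2.034,60.81,39.19,east_asia,humid
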