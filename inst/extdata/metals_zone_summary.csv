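zone,species,mean,sd,max,min,n_days
North,Al,1423.40,254.60,1938.61,1074.84,79
North,Cr(VI),104.16,66.28,581.90,57.51,79
North,Mn,28.39,20.41,63.84,9.55,79
North,Cu,33.75,17.52,123.84,10.91,79
North,Zn,57.99,16.31,129.37,32.53,79
North,As,44.92,68.95,510.12,NA,79
North,Pb,27.13,40.25,131.68,NA,79
South,Al,1420.90,248.11,1790.71,1051.70,52
South,Cr(VI),64.08,5.74,75.69,55.77,52
South,Mn,14.56,5.57,23.29,4.77,52
South,Cu,26.48,13.12,73.16,10.30,52
South,Zn,53.60,9.97,69.11,38.12,52
South,As,13.99,15.42,42.09,NA,52
South,Pb,10.97,22.14,58.43,NA,52
Populated,Al,1658.94,185.82,2017.00,1316.31,79
Populated,Cr(VI),66.03,5.78,77.03,51.90,79
Populated,Mn,16.90,6.35,31.90,4.50,79
Populated,Cu,30.07,23.83,152.44,4.01,79
Populated,Zn,55.85,12.87,112.16,34.72,79
Populated,As,13.87,15.08,49.57,NA,79
Populated,Pb,26.23,34.71,94.13,NA,79
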