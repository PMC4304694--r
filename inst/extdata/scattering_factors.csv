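source,element,z,a1,a2,a3,a4,a5,b1,b2,b3,b4,b5
electron,H,1,0.0349,0.1201,0.197,0.0573,0.1195,0.5347,3.5867,12.3471,18.9525,38.6269
xray,H,1,0.493002,0.322912,0.140191,0.04081,0.003038,10.5109,26.1257,3.14236,57.7997,0.0
electron,C,6,0.0893,0.2563,0.757,1.0487,0.3575,0.2465,1.71,6.4094,18.6113,50.2523
xray,C,6,2.31,1.02,1.5886,0.865,0.2156,20.8439,10.2075,0.5687,51.6512,0.0
electron,N,7,0.1022,0.3219,0.7982,0.8197,0.1715,0.2451,1.7481,6.1925,17.3894,48.1431
xray,N,7,12.2126,3.1322,2.0125,1.1663,-11.529,0.0057,9.8933,28.9975,0.5826,0.0
electron,O,8,0.0974,0.2921,0.691,0.699,0.2039,0.2067,1.3815,4.6943,12.7105,32.4726
xray,O,8,3.0485,2.2868,1.5463,0.867,0.2508,13.2771,5.7011,0.3239,32.9089,0.0
electron,P,15,0.2548,0.6106,1.4541,2.3204,0.8477,0.2908,1.874,8.5176,24.3434,63.2996
xray,P,15,6.4345,4.1791,1.78,1.4908,1.1149,1.9067,27.157,0.526,68.1645,0.0
electron,S,16,0.2497,0.5628,1.3899,2.1865,0.7715,0.2681,1.6711,7.0267,19.5377,50.3888
xray,S,16,6.9053,5.2034,1.4379,1.5863,0.8669,1.4679,22.2151,0.2536,56.172,0.0
electron,Mg,12,0.2314,0.6866,0.9677,2.1882,1.1339,0.3278,2.272,10.9241,39.2898,101.9748
xray,Mg,12,5.4204,2.1735,1.2269,2.3073,0.8584,2.8275,79.2611,0.3808,7.1937,0.0
electron,Fe,26,0.3946,1.2725,1.7031,2.314,1.4795,0.2717,2.0443,7.6007,29.9714,86.2265
xray,Fe,26,11.7695,7.3573,3.5222,2.3045,1.0369,4.7611,0.3072,15.3535,76.8805,0.0
electron,Ni,28,0.386,1.1765,1.5451,2.073,1.3814,0.2478,1.766,6.3107,25.2204,74.3146
xray,Ni,28,12.8376,7.292,4.4438,2.38,1.0341,3.8785,0.2565,12.1763,66.3421,0.0
electron,Zn,30,0.4288,1.2646,1.4472,1.8294,1.0934,0.2593,1.7998,6.75,25.586,73.5284
xray,Zn,30,14.0743,7.0318,5.1652,2.41,1.3041,3.2655,0.2333,10.3163,58.7097,0.0
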