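array,element,PD,T1_ms,T2_ms,concentration_mM
NiCl2,1,1,2015.2,1441.82,0.2631
NiCl2,2,1,1424.96,1019.52,0.5745
NiCl2,3,1,1007.6,720.91,1.015
NiCl2,4,1,712.48,509.76,1.6378
NiCl2,5,1,503.8,360.45,2.5187
NiCl2,6,1,356.24,254.88,3.7644
NiCl2,7,1,251.9,180.23,5.5261
NiCl2,8,1,178.12,127.44,8.0176
NiCl2,9,1,125.95,90.11,11.541
NiCl2,10,1,89.06,63.72,16.5239
NiCl2,11,1,62.97,45.06,23.5708
NiCl2,12,1,44.53,31.86,33.5367
NiCl2,13,1,31.49,22.53,47.6304
NiCl2,14,1,22.26,15.93,67.5621
MnCl2,1,1,2425.53,602.21,0.013
MnCl2,2,1,2207.01,462.23,0.0189
MnCl2,3,1,1951.23,345.41,0.0275
MnCl2,4,1,1669.66,252.54,0.0401
MnCl2,5,1,1379.91,181.52,0.0583
MnCl2,6,1,1101.72,128.81,0.0848
MnCl2,7,1,851.83,90.55,0.1234
MnCl2,8,1,640.46,63.23,0.1795
MnCl2,9,1,470.56,43.94,0.2612
MnCl2,10,1,339.51,30.43,0.3801
MnCl2,11,1,241.6,21.02,0.5531
MnCl2,12,1,170.19,14.5,0.8048
MnCl2,13,1,119.01,9.99,1.1711
MnCl2,14,1,82.78,6.88,1.704
PD,1,0.05,308,264,4.43
PD,2,0.1,308,264,4.43
PD,3,0.15,308,264,4.43
PD,4,0.2,308,264,4.43
PD,5,0.25,308,264,4.43
PD,6,0.3,308,264,4.43
PD,7,0.4,308,264,4.43
PD,8,0.5,308,264,4.43
PD,9,0.6,308,264,4.43
PD,10,0.7,308,264,4.43
PD,11,0.8,308,264,4.43
PD,12,0.9,308,264,4.43
PD,13,0.95,308,264,4.43
PD,14,1,308,264,4.43
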