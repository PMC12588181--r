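muscle,f3dmax_N,phi_deg,f2dmax_N,theta_deg,ri_incisor_N,ri_m4_N
MS,7.458,59.70,6.439,63.89,1.284,3.002
MIant,0.994,58.01,0.843,62.85,0.180,0.422
MIpos,2.027,74.39,1.952,62.67,0.263,0.614
MP,1.366,37.12,0.824,89.60,0.121,0.282
ZMant,1.948,14.77,0.497,116.16,0.122,0.286
ZMpos,2.529,46.58,1.837,119.86,0.270,0.630
TZ,1.338,65.73,1.220,135.56,0.191,0.447
TS,6.168,37.93,3.792,94.56,0.992,2.319
TPlat,4.356,8.14,0.617,68.43,0.151,0.352
TPmed,7.131,67.82,6.603,111.36,1.182,2.763
PtLat,0.601,49.30,0.456,5.91,0.001,0.002
PtMed,5.421,59.28,4.660,112.11,0.589,1.376
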