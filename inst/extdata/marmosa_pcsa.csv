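specimen,muscle,pcsa_cm2
M1496,Di,0.0291
M1496,MS,0.1059
M1496,MIant,0.0158
M1496,MIpos,0.0532
M1496,MP,0.0262
M1496,ZMant,0.0426
M1496,ZMpos,0.0196
M1496,TZ,0.0192
M1496,TS,0.0693
M1496,TPlat,0.0684
M1496,TPmed,0.1482
M1496,PtLat,0.0112
M1496,PtMed,0.0956
M2851,Di,0.0338
M2851,MS,0.1469
M2851,MIant,0.0196
M2851,MIpos,0.0399
M2851,MP,0.0269
M2851,ZMant,0.0384
M2851,ZMpos,0.0498
M2851,TZ,0.0264
M2851,TS,0.1215
M2851,TPlat,0.0858
M2851,TPmed,0.1405
M2851,PtLat,0.0118
M2851,PtMed,0.1068
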