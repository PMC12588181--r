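specimen,muscle,mass_g,fibre_length_mm,role
M1496,Di,0.0205,6.689,opener
M1496,MS,0.0513,4.606,closer
M1496,MIant,0.0071,4.272,closer
M1496,MIpos,0.0166,2.964,closer
M1496,MP,0.0084,3.046,closer
M1496,ZMant,0.0232,5.180,closer
M1496,ZMpos,0.0088,4.270,closer
M1496,TZ,0.0065,3.213,closer
M1496,TS,0.0399,5.472,closer
M1496,TPlat,0.0386,5.369,closer
M1496,TPmed,0.0708,4.542,closer
M1496,PtLat,0.0024,2.043,closer
M1496,PtMed,0.0212,2.109,closer
M2851,Di,0.0166,4.673,opener
M2851,MS,0.0485,3.138,closer
M2851,MIant,0.0072,3.495,closer
M2851,MIpos,0.0147,3.500,closer
M2851,MP,0.0091,3.216,closer
M2851,ZMant,0.0178,4.411,closer
M2851,ZMpos,0.0189,3.607,closer
M2851,TZ,0.0068,2.453,closer
M2851,TS,0.0483,3.779,closer
M2851,TPlat,0.0342,3.789,closer
M2851,TPmed,0.0560,3.790,closer
M2851,PtLat,0.0028,2.248,closer
M2851,PtMed,0.0236,2.101,closer
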