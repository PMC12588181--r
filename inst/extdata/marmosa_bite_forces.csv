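bite_point,specimen,f_alive_N,fcalc_closed_N,fcalc_optimal_N,optimal_gape_deg,fitted_stress_Ncm2
incisor,M2851,13.467,10.688,10.754,6.5,37.567
incisor,M1496,13.467,8.759,8.800,5.5,45.908
m4,M2851,37.185,24.992,25.148,6.5,44.360
m4,M1496,37.185,20.481,20.579,5.5,54.209
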