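# Published Monte Carlo radial dose functions for longitudinal source shifts in
# a 30 cm water cube, v1: V(28, 2) (13 cm missing tissue), V(25, 5) (10 cm
# missing tissue) and the centered full-scatter reference (15, 15).
# Values as printed.
isotope,r_cm,g_V28_2,g_V25_5,g_full
Cs137,1,1.000,1.000,1.000
Cs137,2,0.972,0.976,0.977
Cs137,3,0.977,0.985,0.988
Cs137,4,0.950,0.964,0.970
Cs137,5,0.921,0.941,0.950
Cs137,6,0.906,0.933,0.944
Cs137,7,0.868,0.903,0.917
Cs137,8,0.862,0.904,0.923
Cs137,9,0.833,0.881,0.901
Cs137,10,0.788,0.842,0.867
Ir192,1,1.000,1.000,1.000
Ir192,2,1.016,1.023,1.026
Ir192,3,0.990,1.007,1.014
Ir192,4,0.984,1.012,1.024
Ir192,5,0.962,1.003,1.021
Ir192,6,0.969,1.024,1.049
Ir192,7,0.903,0.968,0.999
Ir192,8,0.841,0.914,0.951
Ir192,9,0.815,0.898,0.940
Ir192,10,0.768,0.857,0.904
Pd103,1,1,1,1
Pd103,2,0.564,0.565,0.565
Pd103,3,0.3086,0.31,0.31
Pd103,4,0.1686,0.17,0.17
Pd103,5,0.0898,0.091,0.091
Pd103,6,0.0549,0.056,0.056
Pd103,7,0.0272,0.028,0.028
Pd103,8,0.0154,0.016,0.016
Pd103,9,0.011,0.0116,0.0117
Pd103,10,0.0041,0.0043,0.0043
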