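# Published Monte Carlo radial dose functions for the H(25, 5) configuration
# (source shifted 10 cm along its transverse axis in a 30 cm water cube,
# 5 cm overlying water), v1. Side "away" = opposite the missing tissue,
# side "toward" = facing the missing tissue. Values as printed (3 decimals).
isotope,r_cm,g_away,g_toward
Pd103,1.0,1.000,1.000
Pd103,1.5,0.770,0.770
Pd103,2.0,0.585,0.585
Pd103,2.5,0.410,0.410
Pd103,3.0,0.318,0.318
Pd103,3.5,0.238,0.238
Pd103,4.0,0.169,0.167
Pd103,4.5,0.127,0.124
Pd103,5.0,0.090,0.083
Cs137,1.0,1.000,1.000
Cs137,1.5,0.988,0.988
Cs137,2.0,0.981,0.979
Cs137,2.5,0.974,0.971
Cs137,3.0,0.968,0.962
Cs137,3.5,0.961,0.951
Cs137,4.0,0.954,0.938
Cs137,4.5,0.947,0.922
Cs137,5.0,0.940,0.894
Ir192,1.0,1.000,1.000
Ir192,1.5,1.020,1.019
Ir192,2.0,1.024,1.021
Ir192,2.5,1.022,1.016
Ir192,3.0,1.014,1.004
Ir192,3.5,1.013,0.994
Ir192,4.0,1.024,0.994
Ir192,4.5,1.02,0.973
Ir192,5.0,1.019,0.916
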