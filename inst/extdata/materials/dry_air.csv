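# Photon interaction data, dry air, sea level (rho = 1.205e-3 g/cm^3), v1.
# mu/rho and muen/rho (cm^2/g) transcribed from the standard NIST
# (Hubbell & Seltzer / XCOM) compilation; coarse grid, log-log interpolated.
# Partial fractions: free-electron Klein-Nishina incoherent, transcribed
# coherent column, photoelectric as remainder; renormalized to sum to 1.
energy_MeV,mu_rho,muen_rho,f_pe,f_compton,f_rayleigh
0.001,3606,3599,0.999605,5.5e-05,0.00034
0.0015,1191,1188,0.998841,0.000167,0.000992
0.002,527.9,526.2,0.997475,0.000376,0.002149
0.003,162.5,160.8,0.992718,0.001216,0.006066
0.004,77.88,76.36,0.986677,0.002528,0.010795
0.005,40.27,39.31,0.977254,0.004871,0.017875
0.006,23.41,22.7,0.965194,0.008348,0.026458
0.008,9.921,9.446,0.93236,0.019551,0.048089
0.01,5.12,4.742,0.888649,0.037605,0.073746
0.015,1.614,1.334,0.736494,0.117149,0.146357
0.02,0.7779,0.5389,0.555548,0.238821,0.205631
0.03,0.3538,0.1537,0.249434,0.507683,0.242883
0.04,0.2485,0.06833,0.087309,0.70012,0.212571
0.05,0.208,0.04098,0.017664,0.811538,0.170798
0.06,0.1875,0.03041,0,0.865534,0.134466
0.08,0.1662,0.02407,0,0.912669,0.087331
0.1,0.1541,0.02325,0,0.938708,0.061292
0.15,0.1356,0.02496,0,0.967937,0.032063
0.2,0.1233,0.02672,0,0.979865,0.020135
0.3,0.1067,0.02872,0,0.98952,0.01048
0.4,0.09549,0.02949,0,0.993362,0.006638
0.5,0.08712,0.02966,0,0.995336,0.004664
0.6,0.08055,0.02953,0,0.996485,0.003515
0.8,0.07074,0.02882,0,0.99774,0.00226
1,0.06358,0.02789,0,0.998391,0.001609
1.25,0.05687,0.02666,0.000725,0.998114,0.001161
1.5,0.05175,0.02547,0.002421,0.996698,0.000881
2,0.04447,0.02345,0.010021,0.989393,0.000586
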