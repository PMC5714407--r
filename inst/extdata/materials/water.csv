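# Photon interaction data, liquid water (rho = 1.000 g/cm^3), v1.
# mu/rho and muen/rho (cm^2/g) transcribed from the standard NIST
# (Hubbell & Seltzer / XCOM) compilation; coarse grid, log-log interpolated.
# Partial fractions: free-electron Klein-Nishina incoherent, transcribed
# coherent column, photoelectric as remainder; renormalized to sum to 1.
energy_MeV,mu_rho,muen_rho,f_pe,f_compton,f_rayleigh
0.001,4078,4065,0.999622,5.4e-05,0.000324
0.0015,1376,1372,0.998916,0.000161,0.000923
0.002,617.3,615.2,0.997667,0.000357,0.001976
0.003,192.9,191.7,0.993366,0.001139,0.005495
0.004,82.78,81.91,0.986434,0.002645,0.010921
0.005,42.58,41.88,0.976699,0.005123,0.018178
0.006,24.64,24.05,0.964151,0.00882,0.027029
0.008,10.37,9.915,0.929731,0.020799,0.04947
0.01,5.329,4.944,0.883637,0.040176,0.076187
0.015,1.673,1.374,0.722504,0.125673,0.151823
0.02,0.8096,0.5503,0.532383,0.255166,0.212451
0.03,0.3756,0.1557,0.222226,0.531768,0.246006
0.04,0.2683,0.06947,0.067229,0.721068,0.211703
0.05,0.2269,0.04223,0.004397,0.827247,0.168356
0.06,0.2059,0.0319,0,0.869394,0.130606
0.08,0.1837,0.02597,0,0.915308,0.084692
0.1,0.1707,0.02546,0,0.940611,0.059389
0.15,0.1505,0.02764,0,0.968962,0.031038
0.2,0.137,0.02967,0,0.980517,0.019483
0.3,0.1186,0.03192,0,0.989863,0.010137
0.4,0.1061,0.03279,0,0.99358,0.00642
0.5,0.09687,0.03299,0,0.995489,0.004511
0.6,0.08956,0.03284,0,0.996601,0.003399
0.8,0.07865,0.03206,0,0.997815,0.002185
1,0.07072,0.03103,9.6e-05,0.998349,0.001555
1.25,0.06323,0.02965,0.000631,0.998246,0.001123
1.5,0.05754,0.02833,0.002363,0.996785,0.000852
2,0.04942,0.02608,0.009443,0.98999,0.000567
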