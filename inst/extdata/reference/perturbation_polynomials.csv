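# Published polynomial correction factors for the missing-tissue perturbation of
# the radial dose function, v1: PF(r) = a0 + a1 r + ... + a6 r^6 with r in cm,
# fitted to Monte Carlo g(r) ratios g_(30-x,x)(r) / g_(15,15)(r) for a source
# shifted along its transverse axis in a 30 cm water cube.
# Label "(30-x+x)" encodes the overlying water thickness x (cm); the ratio is
# physically defined toward the missing tissue only up to r = x, hence r_max = x.
# Data note: the Cs137 (24+6) row is transcribed as printed but is internally
# inconsistent with the tabulated ratios (it falls to ~0.55 by r = 4 cm); treat
# values beyond ~2 cm from that row with suspicion.
isotope,label,a0,a1,a2,a3,a4,a5,a6,r_min,r_max
Ir192,(28+2),1.009,-2.976E-02,3.632E-02,-1.476E-02,-1.026E-03,0.0,0.0,1,2
Ir192,(26+4),1.007,-4.012E-02,6.844E-02,-4.830E-02,1.431E-02,-1.564E-03,0.0,1,4
Ir192,(25+5),1.005,-2.917E-02,4.338E-02,-2.585E-02,6.332E-03,-5.685E-04,0.0,1,5
Ir192,(24+6),9.982E-01,3.291E-03,-6.178E-03,5.870E-03,-2.812E-03,5.666E-04,-4.179E-05,1,6
Ir192,(22+8),9.973E-01,8.083E-03,-1.025E-02,5.884E-03,-1.737E-03,2.370E-04,-1.230E-05,1,8
Pd103,(28+2),1.003,-4.518E-03,9.935E-03,-7.712E-03,-2.711E-04,0.0,0.0,1,2
Pd103,(26+4),9.985E-01,7.622E-03,-1.125E-02,6.065E-03,-1.098E-03,0.0,0.0,1,4
Pd103,(25+5),9.976E-01,1.043E-02,-1.202E-02,5.117E-03,-7.043E-04,0.0,0.0,1,5
Pd103,(24+6),9.978E-01,1.266E-02,-2.361E-02,1.897E-02,-7.329E-03,1.344E-03,-9.413E-05,1,6
Pd103,(22+8),9.963E-01,1.745E-02,-2.429E-02,1.420E-02,-3.955E-03,5.202E-04,-2.600E-05,1,8
Cs137,(28+2),1.013,-4.767E-02,5.188E-02,-1.811E-02,0.0,0.0,0.0,1,2
Cs137,(26+4),9.888E-01,6.047E-02,-1.100E-01,9.290E-02,-4.031E-02,8.560E-03,-7.091E-04,1,4
Cs137,(25+5),9.971E-01,1.511E-02,-2.354E-02,1.629E-02,-5.977E-03,1.081E-03,-7.777E-05,1,5
Cs137,(24+6),9.994E-01,3.193E-02,-3.879E-02,1.644E-03,-4.362E-04,6.241E-05,-4.568E-06,1,6
Cs137,(22+8),9.943E-01,2.180E-02,-2.545E-02,1.269E-02,-3.099E-03,3.585E-04,-1.591E-05,1,8
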