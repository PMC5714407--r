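# Pd-103 photon emission spectrum, v1.
# Transcribed from a standard nuclear decay-data compilation (NuDat-style).
# Rh K characteristic x-rays following electron capture; intensities per decay.
# Gamma lines below 0.1% intensity omitted.
energy_MeV,probability
0.020074,0.224
0.020216,0.423
0.022720,0.105
0.023180,0.019
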