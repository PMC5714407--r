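# Cs-137 photon emission spectrum, v1.
# Transcribed from a standard nuclear decay-data compilation (NuDat-style).
# Single line: the 661.7 keV gamma of the Ba-137m daughter. Ba K x-rays are
# absorbed in the stainless pellet shell and omitted from this bare-core model.
energy_MeV,probability
0.6617,1.0
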