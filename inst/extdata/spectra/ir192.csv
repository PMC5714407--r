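# Ir-192 photon emission spectrum, v1.
# Transcribed from a standard nuclear decay-data compilation (NuDat-style).
# Principal gamma lines plus Pt/Os K x-rays; intensities per decay.
# Lines below 0.05% intensity omitted; minor x-ray satellites consolidated.
energy_MeV,probability
0.06149,0.012
0.06300,0.0205
0.06512,0.0264
0.06683,0.0046
0.07141,0.0024
0.13634,0.002
0.20131,0.0047
0.20579,0.0334
0.28327,0.00266
0.29596,0.2871
0.30846,0.2970
0.31651,0.8286
0.37449,0.00727
0.41647,0.0067
0.46807,0.4784
0.48458,0.0319
0.48906,0.00438
0.58858,0.0452
0.60441,0.0820
0.61246,0.0534
0.88454,0.00291
1.06148,0.00053
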