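# Published Monte Carlo dose rate constants (cGy h^-1 U^-1) for different
# missing-tissue configurations of the three sources, v1.
isotope,label,lambda
Cs137,"(15, 15)",1.093
Cs137,"H(25, 5)",1.090
Cs137,"V(25, 5)",1.088
Cs137,"H(28, 2)",1.091
Cs137,"V(28, 2)",1.055
Ir192,"(15, 15)",1.109
Ir192,"H(25, 5)",1.120
Ir192,"V(25, 5)",1.108
Ir192,"H(28, 2)",1.108
Ir192,"V(28, 2)",1.105
Pd103,"(15, 15)",0.650
Pd103,"H(25, 5)",0.650
Pd103,"V(25, 5)",0.650
Pd103,"H(28, 2)",0.650
Pd103,"V(28, 2)",0.650
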