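concentration_uM,ka,kd,KD
25,583,4.83e-5,2.18e-6
50,322,4.39e-3,1.36e-6
100,119,2.45e-3,2.06e-5
150,27,2.29e-3,8.38e-5
200,95,2.43e-3,2.55e-5
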