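concentration_uM,ka,kd,KD
25,206,4.90e-3,2.38e-5
50,143,2.94e-3,2.06e-5
100,93,2.68e-3,2.86e-5
150,86,2.79e-3,3.25e-5
200,87,3.29e-3,3.78e-6
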