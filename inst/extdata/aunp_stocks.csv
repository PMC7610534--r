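diameter_nm,particles_per_ml
5,4.76e13
10,6.40e12
25,3.72e11
35,1.16e11
50,3.97e10
60,2.30e10
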