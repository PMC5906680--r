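strand,n_a,n_c,n_g,n_t
s01,7,6,7,6
s02,7,6,7,6
s03,7,6,7,6
s04,7,6,7,6
s05,7,6,7,6
s06,7,6,7,6
s07,7,6,7,6
s08,7,6,7,6
s09,7,6,7,6
s10,7,6,7,6
s11,7,6,7,6
s12,7,6,7,6
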