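# Classic textbook (Lehninger) pKa set; alternative to the Expasy default.
group	pka
cterm	2.34
nterm_default	9.69
side_D	3.86
side_E	4.25
side_H	6.00
side_C	8.33
side_Y	10.07
side_K	10.53
side_R	12.48
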