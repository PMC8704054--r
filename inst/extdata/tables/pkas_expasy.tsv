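# Bjellqvist pKa set as deployed by Expasy Compute pI/MW.
# nterm_<X> rows give the residue-specific alpha-amino pKa when the chain
# starts with residue X; nterm_default covers the rest.
group	pka
cterm	3.55
nterm_default	7.50
nterm_A	7.59
nterm_M	7.00
nterm_S	6.93
nterm_P	8.36
nterm_T	6.82
nterm_V	7.44
nterm_E	7.70
nterm_G	7.50
side_D	4.05
side_E	4.45
side_H	5.98
side_C	9.00
side_Y	10.00
side_K	10.00
side_R	12.00
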