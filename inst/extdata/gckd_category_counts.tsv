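category	n_combinations	source
nephrosclerosis	94	printed
IgA nephropathy	71	printed
unknown	48	printed
interstitial nephritis	23	printed
hereditary disorders	17	printed
gout	9	printed
chronic glomerulonephritis	15	assumed
others	9	assumed
analgesic nephropathy	6	assumed
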