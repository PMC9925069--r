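cohort	outcome	or	ci_low	ci_high
UK Biobank	sepsis	0.80	0.66	0.96
FinnGen	sepsis	0.98	0.79	1.21
FinnGen	streptococcal sepsis	0.79	0.48	1.31
FinnGen	respiratory sepsis	0.63	0.29	1.35
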