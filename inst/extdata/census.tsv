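gene	recessive	candidate
EGFR	0	1
KRAS	0	1
BRAF	0	1
MAP2K1	0	1
MET	0	1
ARAF	0	1
ERBB2	0	1
TP53	1	1
STK11	1	1
KEAP1	1	1
RB1	1	1
TTN	0	0
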