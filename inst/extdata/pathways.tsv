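gene	pathway
EGFR	EGFR_family
ERBB2	EGFR_family
ERBB3	EGFR_family
KRAS	MAPK
BRAF	MAPK
ARAF	MAPK
MAP2K1	MAPK
MET	MAPK
TP53	TP53
STK11	AMPK
KEAP1	NRF2
RB1	cell_cycle
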