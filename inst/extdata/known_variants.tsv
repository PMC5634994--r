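gene	chrom	pos	ref	alt	protein_change
EGFR	chr7	55259515	T	G	L858R
EGFR	chr7	55242465	G	A	E746K
KRAS	chr12	25398284	C	T	G12D
KRAS	chr12	25398285	C	A	G12C
BRAF	chr7	40453193	T	C	D594G
MAP2K1	chr15	66729181	G	A	E102K
MET	chr7	16411990	G	C	D1010H
ARAF	chr20	47426121	C	G	S214C
ERBB2	chr17	37880220	G	T	V777L
TP53	chr17	7578406	C	T	R175H
TP53	chr17	7578403	C	A	C176F
TP53	chr17	7578394	T	C	H179R
TP53	chr17	7578413	C	T	V173M
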