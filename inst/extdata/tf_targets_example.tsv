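tf	target	mode
CDX1	POSTN	activation
TWIST2	POSTN	unknown
YY1	POSTN	unknown
TCF4	WNT4	unknown
EGR1	WNT4	unknown
RUNX3	WNT4	unknown
GATA6	CAV1	activation
SREBF1	CAV1	repression
TP53	CAV1	repression
SP1	CAV1	activation
TFDP1	CAV1	unknown
PPARG	CAV1	activation
SNIP1	MYC	activation
SNIP1	CCND1	activation
EBF1	CD79A	activation
EBF1	VCAM1	repression
MEIS2	PAX6	activation
MEIS2	HOXB2	unknown
TP53	CCND1	repression
SP1	MYC	activation
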