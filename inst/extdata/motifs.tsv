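name	pattern	note
CRE	TGACGTCA	CREB consensus
CEBP	TTGCGCAA	C/EBP consensus
TRE	TGA(C/G)TCA	c-Jun / AP-1 consensus
ZFP143_RBPJ	ACTACAnnTCCCA	composite ZFP143-RBPJ site found in CREB-bound promoters
CEBP_JUN_LONG	CCCACCATGCTTTGGTCA	long composite, half C/EBP (TTTG) half c-Jun (GTCA), as printed first
CEBP_JUN_LONG_ALT	CCCACCATGCTTTTGGTCA	variant of the long composite printed with an extra T; shipped unreconciled
CEBP_JUN	GACAAGTT(T/A)GGTCA	composite C/EBP - c-Jun motif
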