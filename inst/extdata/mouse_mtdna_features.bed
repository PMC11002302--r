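chrM_synthetic	69	1024	12sRNA	0	+
chrM_synthetic	2750	3707	Nd1	0	+
chrM_synthetic	5159	5191	O_L	0	+
chrM_synthetic	5327	6872	CoxI	0	+
chrM_synthetic	10166	11544	Nd4	0	+
chrM_synthetic	14144	15288	Cytb	0	+
chrM_synthetic	15355	15422	trnP	0	+
chrM_synthetic	15422	16299	D-loop	0	.
chrM_synthetic	15423	15459	TAS	0	.
chrM_synthetic	15459	16059	ISR	0	.
chrM_synthetic	16059	16085	CSB1	0	.
chrM_synthetic	16105	16133	CSB2	0	.
chrM_synthetic	16148	16166	CSB3	0	.
chrM_synthetic	16149	16170	O_H	0	.
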