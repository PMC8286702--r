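gene_a	gene_b	dup_type	ka	ks	time_mya_reported
PgrTIP1.2	PgrTIP1.5	segmental	0.074	1.54	5.12
PgrTIP3.1	PgrTIP3.2	segmental	0.254	1.19	3.97
PgrPIP1.5	PgrPIP1.1	segmental	0.078	0.86	2.88
PgrPIP2.5	PgrPIP2.2	segmental	0.123	1.26	4.21
PgrPIP2.7	PgrPIP2.3	segmental	0.102	1.38	4.59
PgrPIP2.6	PgrPIP2.7	segmental	0.073	1.30	4.32
PgrTIP1.2	PgrTIP1.1	segmental	0.096	2.09	6.97
PgrTIP1.2	PgrTIP1.7	tandem	0.101	0.52	1.74
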