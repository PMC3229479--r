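gene	rsid	chrom	risk_allele	raf	or
EVI5	rs11810217	1	A	0.25	1.15
CD58	rs1335532	1	A	0.87	1.22
IL7R	rs6897932	5	G	0.73	1.11
HLA-DRB	rs3135388	6	A	0.13	3.08
IL2RA	rs3118470	10	G	0.32	1.12
CLEC16A	rs7200786	16	A	0.46	1.15
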