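structure	label	mode	ghz
WT	AMBER98	1	29.21
WT	AMBER98	2	34.77
WT	AMBER98	3	39.55
WT	CHARMM27	1	24.93
WT	CHARMM27	2	27.26
WT	CHARMM27	3	32.77
WT	OPLSaa	1	28.98
WT	OPLSaa	2	34.05
WT	OPLSaa	3	37.96
Fmut	AMBER98	1	30.00
Fmut	AMBER98	2	35.56
Fmut	AMBER98	3	40.76
Fmut	CHARMM27	1	24.38
Fmut	CHARMM27	2	27.34
Fmut	CHARMM27	3	32.71
Fmut	OPLSaa	1	29.26
Fmut	OPLSaa	2	33.66
Fmut	OPLSaa	3	37.59
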