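mutant	forcefield	ddd
SDmut	AMBER98	-1.71
SDmut	CHARMM27	-1.61
SDmut	OPLSaa	-0.22
CRmut	AMBER98	3.79
CRmut	CHARMM27	0.78
CRmut	OPLSaa	1.41
Pmut	AMBER98	0.50
Pmut	CHARMM27	-1.47
Pmut	OPLSaa	-1.20
Sum	AMBER98	2.58
Sum	CHARMM27	-2.30
Sum	OPLSaa	-0.01
Fmut	AMBER98	0.36
Fmut	CHARMM27	-2.11
Fmut	OPLSaa	-0.07
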