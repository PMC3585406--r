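mutant	monomer	forcefield	ddg
SDmut	C	AMBER98	51.07
SDmut	C	CHARMM27	109.92
SDmut	C	OPLSaa	90.89
SDmut	D	AMBER98	42.60
SDmut	D	CHARMM27	107.56
SDmut	D	OPLSaa	97.66
CRmut	C	AMBER98	194.73
CRmut	C	CHARMM27	276.20
CRmut	C	OPLSaa	56.20
CRmut	D	AMBER98	203.56
CRmut	D	CHARMM27	276.14
CRmut	D	OPLSaa	81.06
Pmut	C	AMBER98	3.48
Pmut	C	CHARMM27	106.25
Pmut	C	OPLSaa	139.76
Pmut	D	AMBER98	9.07
Pmut	D	CHARMM27	114.50
Pmut	D	OPLSaa	167.26
Fmut	C	AMBER98	249.59
Fmut	C	CHARMM27	508.35
Fmut	C	OPLSaa	292.48
Fmut	D	AMBER98	274.07
Fmut	D	CHARMM27	493.99
Fmut	D	OPLSaa	314.02
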