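residue	structure	pka
Glu175	WT	NA
Glu175	Pmut	2.926
His178	WT	NA
His178	Pmut	3.573
Asp201	WT	0
Asp201	Pmut	14
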