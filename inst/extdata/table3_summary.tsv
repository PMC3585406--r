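mutant	ave_cd	adjusted
SDmut	83.28	6.66
CRmut	181.32	15.77
Pmut	90.05	7.29
Sum	354.65	31.89
Fmut	355.42	31.97
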