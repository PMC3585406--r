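site	residue	count	n_total
165	D	428	500
165	S	57	500
165	N	10	500
165	Y	1	500
165	-	4	500
175	E	380	500
175	L	103	500
175	T	4	500
175	I	4	500
175	-	2	500
175	X	7	500
178	Q	203	500
178	H	167	500
178	T	114	500
178	D	10	500
178	-	2	500
178	X	4	500
206	R	386	500
206	C	45	500
206	Y	38	500
206	W	11	500
206	-	1	500
206	X	19	500
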