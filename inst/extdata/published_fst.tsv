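pop_a	pop_b	watershed	species	weighted	unweighted	weir	dxy
SB	ST	Same	Nesticus barri	0.33	0.12	0.20	0.14
BT	GV	Same	Nesticus barri	0.42	0.13	0.29	0.25
BT	ST	Different	Nesticus barri	0.42	0.14	0.33	0.31
BT	SB	Different	Nesticus barri	0.43	0.14	0.32	0.30
GV	ST	Different	Nesticus barri	0.49	0.15	0.45	0.33
GV	SB	Different	Nesticus barri	0.52	0.18	0.45	0.32
SB	ST	Same	Ptomaphagus hatchi	0.34	0.18	0.25	0.21
BT	GV	Same	Ptomaphagus hatchi	0.30	0.17	0.16	0.22
BT	ST	Different	Ptomaphagus hatchi	0.34	0.17	0.27	0.25
BT	SB	Different	Ptomaphagus hatchi	0.32	0.17	0.15	0.24
GV	ST	Different	Ptomaphagus hatchi	0.36	0.19	0.31	0.25
GV	SB	Different	Ptomaphagus hatchi	0.36	0.20	0.22	0.24
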