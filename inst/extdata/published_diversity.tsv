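species	cave	length_m	pi_gl	ne_gl	pi_hard	ne_hard
Nesticus barri	ST	370	1.2e-3	1.0e5	1.6e-4	1.4e4
Nesticus barri	GV	490	1.4e-3	1.2e5	2.0e-4	1.8e4
Nesticus barri	SB	1219	1.8e-3	1.6e5	2.1e-4	1.9e4
Nesticus barri	BT	3142	2.6e-3	2.3e5	3.3e-4	2.9e4
Ptomaphagus hatchi	ST	370	1.5e-3	1.4e5	1.2e-4	1.0e4
Ptomaphagus hatchi	GV	490	1.9e-3	1.7e5	2.7e-4	2.4e4
Ptomaphagus hatchi	SB	1219	2.2e-3	2.0e5	3.3e-4	2.9e4
Ptomaphagus hatchi	BT	3142	2.4e-3	2.2e5	3.5e-4	3.1e4
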