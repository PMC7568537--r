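cave	abbrev	survey	length_m	watershed	n_nesticus	n_ptomaphagus
Solomons Temple Cave	ST	FR26	370	Upper Elk River	12	6
Sewanee Blowhole	SB	FR91	1219	Upper Elk River	8	7
Grapevine Cave	GV	FR423	490	Guntersville Lake	10	12
Buggytop Cave	BT	FR16	3142	Guntersville Lake	16	7
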