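section	key	value
initial	BG	0.9900000000000000
initial	NLS	0.0100000000000000
transition	BG:BG	0.9900000000000000
transition	NLS:BG	0.1000000000000000
transition	BG:NLS	0.0100000000000000
transition	NLS:NLS	0.9000000000000000
emission	BG:A	0.0500000000000000
emission	NLS:A	0.0222222222222222
emission	BG:R	0.0500000000000000
emission	NLS:R	0.3000000000000000
emission	BG:N	0.0500000000000000
emission	NLS:N	0.0222222222222222
emission	BG:D	0.0500000000000000
emission	NLS:D	0.0222222222222222
emission	BG:C	0.0500000000000000
emission	NLS:C	0.0222222222222222
emission	BG:Q	0.0500000000000000
emission	NLS:Q	0.0222222222222222
emission	BG:E	0.0500000000000000
emission	NLS:E	0.0222222222222222
emission	BG:G	0.0500000000000000
emission	NLS:G	0.0222222222222222
emission	BG:H	0.0500000000000000
emission	NLS:H	0.0222222222222222
emission	BG:I	0.0500000000000000
emission	NLS:I	0.0222222222222222
emission	BG:L	0.0500000000000000
emission	NLS:L	0.0222222222222222
emission	BG:K	0.0500000000000000
emission	NLS:K	0.3000000000000000
emission	BG:M	0.0500000000000000
emission	NLS:M	0.0222222222222222
emission	BG:F	0.0500000000000000
emission	NLS:F	0.0222222222222222
emission	BG:P	0.0500000000000000
emission	NLS:P	0.0222222222222222
emission	BG:S	0.0500000000000000
emission	NLS:S	0.0222222222222222
emission	BG:T	0.0500000000000000
emission	NLS:T	0.0222222222222222
emission	BG:W	0.0500000000000000
emission	NLS:W	0.0222222222222222
emission	BG:Y	0.0500000000000000
emission	NLS:Y	0.0222222222222222
emission	BG:V	0.0500000000000000
emission	NLS:V	0.0222222222222222
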