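name	pattern	role
nac_pgfrf	P-G-F-R-F-H-P-T-D-[DE]-L-[IV]	core
nac_ylk	Y-L-x(2)-K	core
nac_dlkpw	D-L-x-K-x(2)-P-W-x-L-P	core
nac_ewyff	E-W-Y-F-F	core
nac_gywk	G-Y-W-K-[AT]-T-G-x-D-x(1,2)-[IV]	core
nac_gxkk	G-x-K-K-x-L-V-F-Y	core
nac_mhey	T-x-W-x-M-H-E-Y	core
nac_lvfy	L-V-F-Y	core
wrky_core	W-R-K-Y-G-Q-K	partner
efhand_loop	D-x-D-x-[DN]-G	partner
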