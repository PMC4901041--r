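radiation	dsb_per_dna	dsb_std	rbe	rbe_std	let_keV_um
Electron	4.77	0.4	0.82	0.08	0.2
Co-60	5.83	0.33	1.00	0.08	0.2
Neutron	7.36	0.78	1.26	0.15	55
Be	6.24	0.71	1.07	0.14	11.6
Argon	26.09	5.69	4.48	1.01	99.5
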