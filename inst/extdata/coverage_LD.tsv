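species_id	coverage	tier
ld_sp01	20	LD
ld_sp02	9	LD
ld_sp03	4.05	LD
ld_sp04	1.8225	LD
ld_sp05	0.8201	LD
ld_sp06	0.3691	LD
ld_sp07	0.1661	LD
ld_sp08	0.0747	LD
ld_sp09	0.0336	LD
ld_sp10	0.0151	LD
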