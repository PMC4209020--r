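species_id	coverage	tier
md_sp01	20	MD
md_sp02	16	MD
md_sp03	12.8	MD
md_sp04	10.24	MD
md_sp05	8.192	MD
md_sp06	6.5536	MD
md_sp07	5.2429	MD
md_sp08	4.1943	MD
md_sp09	3.3554	MD
md_sp10	2.6844	MD
md_sp11	2.1475	MD
md_sp12	1.718	MD
md_sp13	1.3744	MD
md_sp14	1.0995	MD
md_sp15	0.8796	MD
md_sp16	0.7037	MD
md_sp17	0.5629	MD
md_sp18	0.4504	MD
md_sp19	0.3603	MD
md_sp20	0.2882	MD
md_sp21	0.2306	MD
md_sp22	0.1845	MD
md_sp23	0.1476	MD
md_sp24	0.1181	MD
md_sp25	0.0944	MD
md_sp26	0.0756	MD
md_sp27	0.0604	MD
md_sp28	0.0484	MD
md_sp29	0.0387	MD
md_sp30	0.0309	MD
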