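species_id	coverage	tier
hd_sp01	20	HD
hd_sp02	19.4	HD
hd_sp03	18.818	HD
hd_sp04	18.2535	HD
hd_sp05	17.7059	HD
hd_sp06	17.1747	HD
hd_sp07	16.6594	HD
hd_sp08	16.1597	HD
hd_sp09	15.6749	HD
hd_sp10	15.2046	HD
hd_sp11	14.7485	HD
hd_sp12	14.306	HD
hd_sp13	13.8768	HD
hd_sp14	13.4605	HD
hd_sp15	13.0567	HD
hd_sp16	12.665	HD
hd_sp17	12.2851	HD
hd_sp18	11.9165	HD
hd_sp19	11.559	HD
hd_sp20	11.2123	HD
hd_sp21	10.8759	HD
hd_sp22	10.5496	HD
hd_sp23	10.2331	HD
hd_sp24	9.9261	HD
hd_sp25	9.6283	HD
hd_sp26	9.3395	HD
hd_sp27	9.0593	HD
hd_sp28	8.7875	HD
hd_sp29	8.5239	HD
hd_sp30	8.2682	HD
hd_sp31	8.0201	HD
hd_sp32	7.7795	HD
hd_sp33	7.5462	HD
hd_sp34	7.3198	HD
hd_sp35	7.1002	HD
hd_sp36	6.8872	HD
hd_sp37	6.6806	HD
hd_sp38	6.4801	HD
hd_sp39	6.2857	HD
hd_sp40	6.0972	HD
hd_sp41	5.9142	HD
hd_sp42	5.7368	HD
hd_sp43	5.5647	HD
hd_sp44	5.3978	HD
hd_sp45	5.2358	HD
hd_sp46	5.0788	HD
hd_sp47	4.9264	HD
hd_sp48	4.7786	HD
hd_sp49	4.6353	HD
hd_sp50	4.4962	HD
hd_sp51	4.3613	HD
hd_sp52	4.2305	HD
hd_sp53	4.1036	HD
hd_sp54	3.9804	HD
hd_sp55	3.861	HD
hd_sp56	3.7452	HD
hd_sp57	3.6328	HD
hd_sp58	3.5239	HD
hd_sp59	3.4181	HD
hd_sp60	3.3156	HD
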