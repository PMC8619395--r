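no	genome	size_bp	gc_pct	n_ssr	ssr_ra	ssr_rd	n_cssr	cssr_ra	cssr_rd	nc_ssr	cssr_pct	z_score
S1	Leptolyngbya boryana NIES-2135	6255462	47.02	15780	2.52	16.64	489	0.08	1.05	1006	6.38	0.13
S2	Leptolyngbya boryana PCC 6306	7262454	47.02	17953	2.47	16.30	538	0.07	1.01	1110	6.19	0.07
S3	Leptolyngbya boryana dg5	6176364	46.99	15600	2.53	16.67	485	0.08	1.06	1001	6.42	0.06
S4	Leptolyngbya sp. FACHB-161	6743911	46.97	16858	2.50	16.49	513	0.08	1.03	1061	6.3	0.01
S5	Leptolyngbya sp. FACHB-238	7173154	46.98	17775	2.48	16.33	539	0.08	1.02	1113	6.27	0.05
S6	Leptolyngbya sp. FACHB-239	7147343	46.98	17716	2.48	16.34	539	0.08	1.02	1113	6.29	0.05
S7	Leptolyngbya sp. FACHB-402	7138201	46.98	17693	2.48	16.34	539	0.08	1.03	1113	6.3	0.05
S8	Leptolyngbya boryana IAM M-101	6176363	46.99	15600	2.53	16.67	485	0.08	1.06	1001	6.42	0.06
S9	Leptolyngbya sp. UWPOB_LEPTO1	6800371	46.86	16881	2.48	16.36	489	0.07	0.98	1007	5.97	0.11
S10	Leptolyngbya sp. FACHB-1624	6648037	46.89	16537	2.49	16.41	476	0.07	0.96	972	5.88	0.29
S11	Leptolyngbya sp. FACHB-17	5574121	48.17	11970	2.15	14.28	303	0.05	0.74	617	5.16	0.28
S12	Leptolyngbya sp. NIES-2104	6386309	47.43	13034	2.04	13.44	309	0.05	0.65	631	4.85	0.23
S13	Leptolyngbya sp. NIES-3755	6244811	46.65	12513	2.00	13.20	286	0.05	0.61	580	4.64	0.34
S14	Leptolyngbya sp. FACHB-321	6715002	49.97	15990	2.38	16.10	497	0.07	1.02	1017	6.37	0.25
S15	Leptolyngbya sp. ULC077bin1	5462880	48.17	14135	2.59	17.25	397	0.07	0.99	815	5.77	0.16
S16	Leptolyngbya sp. hensonii	5940029	52.32	14206	2.39	16.01	433	0.07	1.00	886	6.24	0.23
S17	Leptolyngbya sp. FACHB-8	6927450	50.67	17792	2.57	16.93	625	0.09	1.21	1295	7.28	-0.03
S18	Leptolyngbya sp. FACHB-16	8006770	50.32	20514	2.56	16.89	726	0.09	1.22	1509	7.36	-0.12
S19	Leptolyngbya ohadii IS1	7902459	52.09	17477	2.21	15.29	644	0.08	1.15	1357	7.77	-0.46
S20	Leptolyngbya sp. JSC-1	7866824	50.72	15873	2.09	14.41	537	0.07	1.03	1183	7.46	-1.45
S21	Leptolyngbya sp. IPPAS B-1204	8174684	50.83	16980	2.08	14.33	538	0.07	0.96	1165	6.87	-1.05
S22	Leptolyngbya sp. DLM2.Bin15	5006105	53.93	11640	2.33	16.29	366	0.07	1.08	759	6.53	-0.04
S23	Leptolyngbya sp. CCY15150	5756177	53.40	13178	2.29	15.98	381	0.07	0.96	781	5.93	0.18
S24	Leptolyngbya cf. ectocarpi LEGE 11479	6774485	49.35	19842	2.93	19.64	726	0.11	1.46	1482	7.47	0.37
S25	Leptolyngbya sp. Heron Island J	8064167	48.05	22589	2.80	18.77	800	0.10	1.37	1646	7.29	0.16
S26	Leptolyngbya sp. SIO4C1	5299754	54.81	16272	3.07	21.33	598	0.11	1.63	1240	7.63	-0.05
S27	Leptolyngbya sp. BC1307	4916582	52.93	15073	3.07	20.91	578	0.12	1.64	1180	7.83	0.33
S28	Leptolyngbya foveolarum ULC129bin1	4750982	51.01	13708	2.89	19.52	463	0.10	1.37	955	6.97	0.07
S29	Leptolyngbya sp. SIO1E4	8792215	51.44	24000	2.73	18.19	907	0.10	1.43	1865	7.78	0.19
S30	Leptolyngbya sp. SIO1D8	7757311	47.92	20287	2.62	17.41	695	0.09	1.23	1428	7.04	0.19
S31	Leptolyngbya sp. SIOISBB	8337037	51.86	21217	2.55	17.06	698	0.08	1.17	1441	6.8	0.06
S32	Leptolyngbya sp. RL_3_1	3943200	56.13	11086	2.81	19.44	384	0.10	1.40	796	7.19	-0.03
S33	Leptolyngbya sp. LCM1.Bin17	4618091	55.39	12930	2.80	19.44	507	0.11	1.60	1050	8.13	-0.02
S34	Leptolyngbya sp. BL0902	4710209	57.65	12530	2.66	19.04	418	0.09	1.31	866	6.92	-0.02
S35	Leptolyngbya sp. KIOST-1	6320122	59.44	19308	3.06	22.05	788	0.12	1.88	1642	8.51	-0.19
S36	Leptolyngbya sp. ULC186bin1	5080999	57.41	14809	2.92	20.70	564	0.11	1.66	1185	8.01	-0.36
S37	Leptolyngbya sp. FACHB-60	5913379	55.56	16386	2.77	19.33	609	0.10	1.48	1246	7.61	0.28
S38	Leptolyngbya sp. DLM2.Bin27	4277754	59.01	14185	3.32	24.08	585	0.14	2.06	1214	8.56	-0.07
S39	Leptolyngbya sp. ULC073bin1	4608713	57.79	14600	3.17	22.73	616	0.13	2.03	1312	8.99	-0.72
S40	Leptolyngbya antarctica ULC041bin1	4711992	58.22	15225	3.23	23.31	654	0.14	2.11	1380	9.07	-0.50
S41	Leptolyngbya sp. 7M	6990850	49.92	15706	2.25	15.09	428	0.06	0.83	875	5.58	0.25
S42	Leptolyngbya sp. AVDCRST_MAG94	5510397	52.11	13152	2.39	16.45	378	0.07	0.98	770	5.86	0.31
S43	Leptolyngbya sp. ES-bin-22	5129489	51.62	12342	2.41	16.29	352	0.07	0.96	735	5.96	-0.17
S44	Leptolyngbya sp. FACHB-711	6345842	50.70	14268	2.25	15.41	452	0.07	1.01	931	6.53	0.10
S45	Leptolyngbya sp. SIO3F4	8111628	45.71	23151	2.85	19.06	873	0.11	1.47	1801	7.78	0.09
S46	Leptolyngbya sp. SIO4C5	5604438	53.04	14754	2.63	18.26	496	0.09	1.28	1027	6.97	-0.01
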