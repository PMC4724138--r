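snp_id	gene	chr	position	effect_allele	other_allele	hwe_p_normal	eaf_study	eaf_discovery	fst_printed	discovery_study	ancestry	is_proxy	discovery_or
rs1558902	FTO	16	52361075	A	T	0.58	0.13	0.42	0.105	Speliotes2010	European	FALSE	NA
rs2867125	TMEM18	2	612827	C	T	0.20	0.91	0.83	0.014	Speliotes2010	European	FALSE	NA
rs571312	MC4R	18	55990749	A	C	0.67	0.23	0.24	0.000	Speliotes2010	European	FALSE	NA
rs10938397	GNPDA2	4	44877284	G	A	0.54	0.31	0.43	0.015	Speliotes2010	European	FALSE	NA
rs10767664	BDNF	11	27682562	A	T	0.30	0.55	0.78	0.059	Speliotes2010	European	FALSE	NA
rs2815752	NEGR1	1	72585028	A	G	0.97	0.92	0.61	0.134	Speliotes2010	European	FALSE	NA
rs7359397	SH2B1	16	28793160	T	C	0.17	0.16	0.40	0.071	Speliotes2010	European	FALSE	NA
rs9816226	ETV5	3	187317193	T	A	0.36	0.97	0.82	0.060	Speliotes2010	European	FALSE	NA
rs3817334	MTCH2	11	47607569	T	C	0.16	0.33	0.41	0.007	Speliotes2010	European	FALSE	NA
rs29942	KCTD15	19	39001117	C	T	0.76	0.25	0.31	0.004	Speliotes2010	European	TRUE	NA
rs543874	SEC16B	1	176156103	G	A	0.80	0.22	0.19	0.001	Speliotes2010	European	FALSE	1.10
rs987237	TFAP2B	6	50911009	G	A	0.52	0.18	0.18	0.000	Speliotes2010	European	FALSE	NA
rs7138803	FAIM2	12	48533735	A	G	0.01	0.28	0.38	0.011	Speliotes2010	European	FALSE	NA
rs713586	RBJ	2	25011512	C	T	0.77	0.49	0.47	0.000	Speliotes2010	European	FALSE	NA
rs2241423	MAP2K5	15	65873892	G	A	0.67	0.41	0.78	0.142	Speliotes2010	European	FALSE	1.07
rs2287019	QPCTL	19	50894012	C	T	0.09	0.82	0.80	0.001	Speliotes2010	European	FALSE	NA
rs1514175	TNNI3K	1	74764232	A	G	0.91	0.78	0.43	0.128	Speliotes2010	European	FALSE	NA
rs2112347	FLJ35779	5	75050998	T	G	0.88	0.44	0.63	0.036	Speliotes2010	European	FALSE	NA
rs16912921	LRRN6C	9	28403461	A	C	0.19	0.30	0.34	0.002	Speliotes2010	European	TRUE	NA
rs3810291	TMEM160	19	52260843	A	G	0.58	0.29	0.67	0.145	Speliotes2010	European	FALSE	NA
rs1555543	PTBP2	1	96717385	C	A	0.81	0.87	0.59	0.099	Speliotes2010	European	FALSE	NA
rs9579083	MTIF3	13	26915270	C	G	0.87	0.15	0.23	0.010	Speliotes2010	European	TRUE	NA
rs4929949	RPL27A	11	8561169	C	T	0.79	0.40	0.52	0.014	Speliotes2010	European	FALSE	NA
rs206936	NUDT3	6	34410847	G	A	0.30	0.51	0.21	0.098	Speliotes2010	European	FALSE	NA
rs12145833	SDCCAG8	1	241550377	T	G	0.55	0.91	0.87	0.004	Scherag2010	European	FALSE	NA
rs13278851	TNKS/MSRA	8	9788282	A	G	0.28	0.14	0.11	0.002	Scherag2010	European	FALSE	NA
rs9568856	OLFM4	13	52962982	A	G	0.34	0.33	0.16	0.039	Bradfield2012	European	FALSE	NA
rs9299	HOXB5	17	44024429	A	G	0.44	0.53	0.65	0.015	Bradfield2012	European	FALSE	NA
rs2206734	CDKAL1	6	20802863	G	A	0.66	0.59	0.59	0.000	Okada2012	EastAsian	FALSE	NA
rs11142387	KLF9	9	72188152	C	A	0.96	0.33	0.46	0.018	Okada2012	EastAsian	FALSE	NA
rs261966	PCSK1	5	95875343	G	A	0.53	0.45	0.42	0.001	Wen2012	EastAsian	TRUE	NA
rs12597579	GP2	16	20165368	C	T	0.99	0.73	0.80	0.007	Wen2012	EastAsian	FALSE	NA
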