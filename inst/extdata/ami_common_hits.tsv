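atc_code	drug_name	sw_n10	sw_n01	sw_rr	sw_lo	sw_hi	no_n10	no_n01	no_rr	no_lo	no_hi	comb_rr	comb_lo	comb_hi
N02AG01	Morphine & antispasmodics	256	42	5.92	4.09	8.57	28	2	6.66	2.31	19.36	6.00	4.23	8.50
N02AA01	Morphine	2195	1515	1.69	1.52	1.89	137	67	1.84	1.21	2.79	1.70	1.53	1.89
N02AA05	Oxycodone	2659	2337	1.21	1.10	1.34	252	191	1.40	1.07	1.84	1.23	1.12	1.35
N02AA59	Codeine, combinations	1526	1391	1.09	1.00	1.20	1386	1202	1.14	1.03	1.25	1.11	1.04	1.19
R05FA02	Opium derivatives & expectorant	828	438	1.73	1.52	1.97	71	35	1.59	1.00	2.54	1.72	1.52	1.95
N02BE01	Paracetamol	14481	14036	1.01	0.75	1.05	1412	1290	1.02	0.93	1.12	1.01	0.98	1.05
M01AB05	Diclofenac	1180	1001	1.15	1.04	1.28	504	387	1.26	1.07	1.47	1.18	1.08	1.29
J01FA01	Erythromycin	90	36	2.14	1.39	3.30	156	89	1.66	1.22	2.24	1.81	1.41	2.32
J01AA02	Doxycycline	1095	591	1.76	1.58	1.96	324	213	1.51	1.25	1.83	1.70	1.54	1.86
J01CA04	Amoxicillin	575	353	1.44	1.24	1.66	327	168	2.09	1.69	2.58	1.62	1.44	1.83
J01XE01	Nitrofurantoin	365	249	1.56	1.29	1.89	105	66	1.62	1.12	2.33	1.57	1.33	1.86
J01EA01	Trimethoprim	402	281	1.60	1.33	1.92	149	114	1.38	1.03	1.84	1.53	1.31	1.79
J01CE02	Phenoxymethylpenicillin	847	595	1.34	1.20	1.50	423	277	1.51	1.29	1.77	1.39	1.27	1.53
J01MA02	Ciprofloxacin	830	630	1.35	1.19	1.52	194	134	1.43	1.10	1.86	1.36	1.22	1.52
J01CA08	Pivmecillinam	535	422	1.21	1.05	1.41	309	211	1.45	1.19	1.78	1.29	1.14	1.45
P01AB01	Metronidazole	169	185	0.73	0.57	0.93	51	51	0.60	0.38	0.94	0.70	0.56	0.87
B01AC24	Ticagrelor	96	14	5.14	2.85	9.26	27	6	3.12	1.27	7.67	4.42	2.70	7.24
B01AC04	Clopidogrel	1290	852	1.78	1.57	2.01	391	251	1.44	1.19	1.76	1.68	1.51	1.86
B01AB05	Enoxaparin	126	93	1.34	0.98	1.83	78	43	1.85	1.14	3.00	1.47	1.13	1.92
B01AC06	Acetylsalicylic acid	15489	15240	0.99	0.95	1.03	3141	2803	1.09	1.02	1.17	1.02	0.98	1.05
R03AC03	Terbutaline	968	787	1.16	1.04	1.30	92	77	1.24	0.89	1.73	1.17	1.05	1.30
R03AC02	Salbutamol	618	526	1.12	0.98	1.28	653	532	1.16	1.00	1.34	1.14	1.03	1.26
A02BC05	Esomeprazole	871	802	1.09	0.96	1.25	725	588	1.29	1.13	1.48	1.18	1.08	1.30
A02BC01	Omeprazole	8870	8261	1.12	1.07	1.18	238	213	1.17	0.94	1.45	1.12	1.07	1.18
C01DA02	Glyceryl trinitrate	5020	2949	1.84	1.74	1.94	1758	864	2.15	1.96	2.36	1.92	1.83	2.01
A03FA01	Metoclopramide	709	503	1.49	1.28	1.73	335	220	1.40	1.12	1.75	1.46	1.29	1.66
R05CB01	Acetylcysteine	1677	1375	1.14	1.05	1.24	519	394	1.11	0.96	1.30	1.13	1.05	1.22
N05BA01	Diazepam	1165	957	1.12	0.99	1.26	664	575	1.06	0.93	1.22	1.09	1.00	1.20
C09CA01	Losartan	1728	1738	0.95	0.86	1.05	292	310	0.89	0.73	1.08	0.94	0.86	1.02
C09CA06	Candesartan	1363	1448	0.88	0.79	0.98	360	387	0.92	0.77	1.09	0.89	0.81	0.98
N06AB04	Citalopram	5548	5513	0.97	0.90	1.05	170	182	0.85	0.66	1.11	0.96	0.89	1.03
N06AB06	Sertraline	1358	1360	0.90	0.78	1.04	90	98	0.78	0.53	1.13	0.88	0.77	1.01
C09AA05	Ramipril	1870	1855	0.92	0.83	1.02	709	683	0.94	0.81	1.08	0.93	0.85	1.01
M04AA01	Allopurinol	1897	1952	0.93	0.83	1.03	351	394	0.85	0.70	1.04	0.91	0.83	1.00
A10BA02	Metformin	2659	2896	0.86	0.79	0.94	693	695	0.95	0.83	1.09	0.89	0.82	0.95
C07AB02	Metoprolol	8861	8437	1.05	1.00	1.11	2579	2289	1.11	1.02	1.20	1.07	1.02	1.12
C07AB03	Atenolol	2836	2823	1.01	0.93	1.09	252	285	0.79	0.65	0.96	0.98	0.91	1.05
C08CA01	Amlodipine	2512	2544	0.92	0.85	1.00	706	718	0.96	0.85	1.09	0.93	0.87	1.00
C08CA02	Felodipine	3529	3617	0.91	0.85	0.98	112	93	1.34	0.96	1.87	0.93	0.86	0.99
R01AD09	Mometasone	326	338	0.87	0.73	1.03	83	100	0.74	0.54	1.03	0.84	0.72	0.98
C03CA01	Furosemide	14307	13807	1.04	0.99	1.09	1317	1201	1.05	0.95	1.17	1.04	1.00	1.09
C03DA01	Spironolactone	2716	2674	0.94	0.86	1.03	258	219	1.17	0.92	1.48	0.97	0.89	1.05
H02AB06	Prednisolone	3692	3486	1.05	0.97	1.13	963	823	1.05	0.94	1.17	1.05	0.99	1.12
N05CF01	Zopiclone	5999	6024	0.96	0.90	1.02	1618	1460	1.06	0.97	1.17	0.99	0.94	1.04
N05CF02	Zolpidem	2555	2564	0.97	0.89	1.05	175	191	0.85	0.67	1.07	0.96	0.88	1.03
C10AA01	Simvastatin	5611	5672	0.94	0.88	0.99	1806	1748	0.90	0.82	0.98	0.93	0.88	0.97
H03AA01	Levothyroxine sodium	4843	4863	0.93	0.86	1.01	629	648	0.92	0.80	1.06	0.93	0.87	1.00
B03BA03	Hydroxocobalamin	125	155	0.79	0.61	1.01	49	63	0.66	0.43	1.02	0.76	0.61	0.94
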