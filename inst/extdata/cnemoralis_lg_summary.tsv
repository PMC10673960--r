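lg	n_snps	contig_mb	length_cm	pct_of_map
1	59069	265.37	151.48	7.07
2	10648	54.22	92.54	4.32
3	16584	105.28	104.53	4.88
4	9842	52.78	136.18	6.35
5	9096	52.12	70.11	3.27
6	12030	73.11	134.52	6.28
7	6101	38.83	84.33	3.93
8	10653	70.53	126.84	5.92
9	6495	39.32	81.74	3.81
10	9104	45.96	89.21	4.16
11	5746	38.69	74.47	3.47
12	5197	36.91	109.44	5.11
13	7352	45.71	87.46	4.08
14	8217	58.09	104.52	4.88
15	4387	49.68	110.05	5.13
16	5025	22.32	60.85	2.84
17	3683	39.84	90.25	4.21
18	5173	39.18	93.32	4.35
19	10104	59.01	96.44	4.50
20	7000	45.86	116.55	5.44
21	2720	16.74	72.04	3.36
22	1367	13.34	56.84	2.65
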