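study	N	pct_male	mean_age	sd_age	voxel_size	TR	volumes	duration	components
AnnArbor_a	25	88.0	21.0	7.4	35.4	1.00	295	295.0	17
AnnArbor_b	36	47.2	NA	NA	37.8	1.00	395	395.0	19
Atlanta	28	46.4	30.9	9.9	47.3	2.02	205	414.1	16
Baltimore	23	34.8	29.3	5.5	21.3	2.50	123	307.5	15
Bangor	20	100.0	23.4	5.3	27.0	2.00	265	530.0	20
Beijing	198	38.4	21.2	1.8	35.2	2.00	225	450.0	17
Berlin	26	50.0	29.8	5.2	36.0	2.30	195	448.5	19
Cambridge	198	37.9	21.0	2.3	27.0	3.00	119	357.0	17
Cleveland	31	35.5	43.5	11.1	16.0	2.80	127	355.6	17
Dallas	24	50.0	42.6	20.1	47.3	2.00	115	230.0	13
ICBM	86	47.7	44.2	17.9	27.0	2.00	192	384.0	12
Leiden_2180	12	100.0	23.0	2.5	40.7	2.18	215	468.7	19
Leiden_2200	19	57.9	21.7	2.6	40.7	2.20	215	473.0	19
Leipzig	37	43.2	26.2	5.0	36.0	2.30	195	448.5	20
Milwaukee_a	18	NA	NA	NA	84.4	2.00	175	350.0	22
Milwaukee_b	46	32.6	53.6	5.8	56.2	2.00	175	350.0	16
Munchen	16	62.5	68.4	4.0	43.0	3.00	72	216.0	11
Newark	19	47.4	24.1	3.9	59.1	2.00	135	270.0	14
NewHaven_a	19	52.6	31.0	10.3	70.9	1.00	249	249.0	13
NewHaven_b	16	50.0	26.9	6.3	65.0	1.50	181	271.5	18
NewYork_a	25	80.0	35.0	9.6	27.0	2.00	192	384.0	13
NewYork_a	84	51.2	24.4	10.1	27.0	2.00	192	384.0	13
NewYork_b	20	40.0	29.8	9.9	36.0	2.00	175	350.0	13
Ontario	9	NA	NA	NA	64.0	3.00	105	315.0	15
Orangeburg	20	75.0	40.6	11.0	61.2	2.00	165	330.0	12
Oulu	103	35.9	21.5	0.6	70.4	1.80	245	441.0	15
Oxford	22	54.5	29.0	3.8	31.5	2.00	175	350.0	17
PaloAlto	17	11.8	32.5	8.1	57.9	2.00	235	470.0	20
Pittsburgh	17	58.8	37.9	9.0	31.3	1.50	275	412.5	13
Queensland	19	57.9	25.9	3.9	46.5	2.10	190	399.0	17
SaintLouis	31	45.2	25.1	2.3	64.0	2.50	127	317.5	17
Taipei_a	13	NA	NA	NA	56.3	2.00	295	590.0	25
Taipei_b	8	NA	NA	NA	47.3	2.00	175	350.0	17
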