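genome_id	start_1based	end_1based	detector	raw_score	phage_gene_count	total_gene_count	att_flag
Bath	2818869	2875600	phigaro		17	57	
Bath	2818869	2875600	phispy		17	57	
Bath	2818869	2875600	phastest	118.4	17	57	TRUE
Bath	3090981	3136586	phigaro		27	63	
Bath	3090981	3136586	phispy		27	63	
Bath	3090981	3136586	phastest	131.2	27	63	TRUE
KN2	1828593	1899999	phigaro		22	81	
KN2	1828593	1899999	phispy		22	81	
KN2	1828593	1899999	phastest	125.7	22	81	TRUE
KN2	2309080	2345124	phigaro		16	45	
KN2	2309080	2345124	phispy		16	45	
KN2	2309080	2345124	phastest	112.9	16	45	
IO1	2502234	2549530	phigaro		26	65	
IO1	2502234	2549530	phispy		26	65	
IO1	2502234	2549530	phastest	140.3	26	65	
McNor	491588	520685	phigaro		13	33	
McNor	491588	520685	phispy		13	33	
McNor	491588	520685	phastest	120.6	13	33	
McNor	1493609	1539485	phigaro		21	58	
McNor	1493609	1539485	phispy		21	58	
McNor	1493609	1539485	vibrant	92.5	21	58	
McNor	1900782	1941935	phigaro		16	53	
McNor	1900782	1941935	phispy		16	53	
McNor	1900782	1941935	vibrant	88.1	16	53	
16-5	1897271	1964996	phigaro		20	90	
16-5	1897271	1964996	phispy		20	90	
16-5	1897271	1964996	vibrant	95.7	20	90	
16-5	2518532	2564410	phigaro		29	60	
16-5	2518532	2564410	phispy		29	60	
16-5	2518532	2564410	vibrant	90.3	29	60	
16-5	3229289	3281743	phigaro		18	68	
16-5	3229289	3281743	phispy		18	68	
16-5	3229289	3281743	vibrant	86.9	18	68	
Bath	100000	110000	phigaro		4	20	
Bath	500000	508000	phispy		5	22	
Bath	900000	907000	phastest	38.2	6	24	
KN2	200000	212000	vibrant	21.4	7	26	
KN2	600000	608000	phigaro		8	28	
IO1	300000	309000	phispy		3	24	
IO1	700000	711000	vibrant	33.8	4	26	
McNor	1000000	1009000	phastest	45.1	5	28	
McNor	2500000	2511000	phigaro		6	21	
16-5	400000	410000	vibrant	27.2	7	23	
16-5	800000	807000	phispy		8	25	
MIR	150000	157000	phigaro		3	21	
MIR	450000	462000	phispy		4	23	
MIR	750000	758000	phastest	33.7	5	25	
MIR	1050000	1061000	vibrant	39.5	6	27	
MIR	1350000	1356000	phigaro		7	29	
MIR	1650000	1663000	phastest	51.9	8	31	
IM1	250000	261000	vibrant	24.9	3	18	
IM1	550000	556000	phigaro		4	20	
IM1	850000	862000	phispy		5	22	
IM1	1150000	1157000	phastest	42.4	6	24	
IM1	1450000	1459000	vibrant	31.1	7	26	
IM1	1750000	1760000	phigaro		8	28	
BH	350000	359000	phigaro		3	24	
BH	650000	655000	phastest	36.8	4	26	
BH	950000	963000	phispy		5	28	
BH	1250000	1262000	vibrant	36.4	6	21	
BH	1550000	1561000	phigaro		7	23	
BH	1850000	1860000	vibrant	29.8	8	25	
Mc7	120000	129000	phastest	47.5	3	21	
Mc7	420000	431000	phigaro		4	23	
Mc7	720000	727000	phispy		5	25	
Mc7	1020000	1033000	vibrant	34.6	6	27	
Mc7	1320000	1326000	phastest	40.9	7	29	
Mc7	1620000	1630000	phispy		8	31	
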