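region_id	genome_id	start_1based	end_1based	length_kb_printed	total_proteins	phage_proteins	completeness	quality
Bath-R1	Bath	2818869	2875600	56.7	57	17	76.28	Medium-quality
Bath-R2	Bath	3090981	3136586	45.6	63	27	100.0	High-quality
KN2-R1	KN2	1828593	1899999	71.4	81	22	60.97	Medium-quality
KN2-R2	KN2	2309080	2345124	36.0	45	16	60.91	Medium-quality
IO1-R1	IO1	2502234	2549530	47.3	65	26	100.0	High-quality
McNor-R1	McNor	491588	520685	29.1	33	13	70.28	Medium-quality
McNor-R2	McNor	1493609	1539485	45.9	58	21	73.14	Medium-quality
McNor-R3	McNor	1900782	1941935	41.2	53	16	69.54	Medium-quality
16-5-R1	16-5	1897271	1964996	67.7	90	20	100.0	High-quality
16-5-R2	16-5	2518532	2564410	45.9	60	29	100.0	High-quality
16-5-R3	16-5	3229289	3281743	52.5	68	18	100.0	High-quality
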