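stress	degs	up	down	uniquely_regulated	uniquely_up	uniquely_down	generally_regulated	generally_up	generally_down	background	low_regulated
Cu	2666	1768	898	22	12	10	577	539	38	530	66
AsV	4675	2527	2148	340	64	276	577	539	38	530	66
Cd	2577	1836	741	39	17	20	577	539	38	530	66
Hg	4029	2101	1928	53	31	22	577	539	38	530	66
Cr	2498	1801	688	16	9	7	577	539	38	530	66
V	3869	2486	1383	75	62	13	577	539	38	530	66
FA	2476	1742	734	23	18	5	577	539	38	530	66
juglone	3033	2055	978	23	6	17	577	539	38	530	66
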