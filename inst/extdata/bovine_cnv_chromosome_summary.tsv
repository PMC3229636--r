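chrom	chrom_length	total_cnv_length	n_cnv	mean_len	median_len	max_len	min_len
1	161106243	44913	11	4083	4148	7151	2861
2	140800416	143068	32	4471	4865	10257	2629
3	127923604	173057	27	6410	5435	28029	2861
4	124454208	0	0	0	0	0	0
5	125847759	309452	51	6068	6435	19448	2860
6	122561022	358280	56	6398	5610	20911	2549
7	112078216	272175	95	2865	3421	9881	1901
8	116942821	190373	37	5145	5131	13111	2849
9	108145351	61772	14	4412	3949	7051	2821
10	106383598	96123	25	3845	3727	8481	2569
11	110171769	82123	31	2649	2813	4499	2249
12	85358539	217445	49	4438	5005	9731	2781
13	84419198	152086	64	2376	2758	3939	1969
14	81345643	91924	26	3536	3752	5628	2680
15	84633453	106076	30	3536	3611	10209	2489
16	77906053	30688	6	5115	3562	14248	2740
17	76506943	36720	11	3338	3510	6480	2700
18	66141439	563154	120	4693	6100	18405	2141
19	65312493	22660	6	3777	2987	6723	2489
20	75796353	27332	8	3416	3589	4141	2761
21	69173390	44293	13	3407	3568	5413	2461
22	61848140	19408	4	4852	4033	8821	2521
23	53376148	50750	12	4229	3500	12000	2500
24	65020233	34298	10	3430	3307	5389	2449
25	44060403	0	0	0	0	0	0
26	51750746	69401	33	2103	2301	2761	1841
27	48749334	70250	14	5018	4126	20071	2231
28	46084206	20587	5	4117	3943	5913	2409
29	51998940	0	0	0	0	0	0
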