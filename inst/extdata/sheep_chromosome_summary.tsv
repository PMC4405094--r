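chr	length_mb	n_snps	h2_jaw	h2_weight
1	276	4138	0.103	0.048
2	249	3842	0.031	0.043
3	224	3540	0.032	0.006
4	119	1992	0.027	0.017
5	108	1702	0.01	0.007
6	117	1784	0.052	0.07
7	100	1653	0.051	0
8	91	1535	0.003	0.017
9	95	1546	0.087	0.046
10	86	1416	0.019	0.022
11	62	853	0.049	0
12	79	1218	0.016	0
13	83	1165	0.001	0.018
14	63	786	0.035	0
15	81	1204	0	0
16	72	1091	0	0.001
17	72	1032	0.043	0
18	69	1003	0	0
19	60	846	0	0.009
20	51	801	0.011	0.001
21	50	587	0.008	0
22	51	804	0	0.003
23	62	741	0.047	0.007
24	42	439	0.005	0.001
25	45	685	0.012	0.008
26	44	634	0.003	0.028
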