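GEN	NE
1	45000
2	43546
3	42139
4	40777
5	39460
6	38185
7	36951
8	35757
9	34602
10	33483
11	32402
12	31355
13	30341
14	29361
15	28412
16	27494
17	26606
18	25746
19	24914
20	24109
21	23330
22	22576
23	21847
24	21141
25	20458
26	19797
27	19157
28	18538
29	17939
30	17359
31	16799
32	16256
33	15730
34	15222
35	14730
36	14254
37	13794
38	13348
39	12917
40	12499
41	12096
42	11705
43	11326
44	10961
45	10606
46	10264
47	9932
48	9611
49	9301
50	9000
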