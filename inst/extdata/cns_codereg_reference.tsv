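inv	symbol	pattern	f	f_pct	kmeans_cluster	mean_expression
1	MIR376B	Up-regulated	165	84.61	1	0.722
2	MIR372	Up-regulated	148	75.90	1	0.624
3	MIR149	Down-regulated	195	100.00	2	-5.491
4	MIR214	Down-regulated	195	100.00	2	-4.742
5	MIR574	Down-regulated	195	100.00	2	-4.975
6	MIR595	Down-regulated	195	100.00	2	-4.083
7	MIR765	Down-regulated	195	100.00	2	-5.690
8	MIR92B	Down-regulated	182	93.33	2	-3.622
9	MIR939	Down-regulated	189	96.92	2	-3.225
10	MIR202	Down-regulated	190	97.43	2	-3.369
11	MIR921	Down-regulated	191	97.95	2	-3.527
12	MIR494	Down-regulated	193	98.97	2	-6.053
13	MIR665	Down-regulated	193	98.97	2	-4.835
14	MIR936	Down-regulated	193	98.97	2	-4.799
15	MIR575	Down-regulated	194	99.49	2	-3.731
16	MIR638	Down-regulated	194	99.49	2	-5.799
17	MIR933	Down-regulated	194	99.49	2	-4.271
18	MIR32	Down-regulated	176	90.25	3	-1.7540219
19	MIR557	Down-regulated	176	90.25	3	-1.2031172
20	MIR583	Down-regulated	177	90.77	3	-1.3094348
21	MIR675	Down-regulated	177	90.77	3	-1.8494352
22	MIR370	Down-regulated	178	91.28	3	-1.7722773
23	MIR760	Down-regulated	178	91.28	3	-1.4657573
24	MIR198	Down-regulated	179	91.80	3	-2.2433618
25	MIR210	Down-regulated	179	91.80	3	-2.3769263
26	MIR627	Down-regulated	179	91.80	3	-1.0966398
27	MIR650	Down-regulated	179	91.80	3	-2.0081156
28	MIR647	Down-regulated	180	92.31	3	-1.6223603
29	MIR632	Down-regulated	181	92.82	3	-1.5932408
30	MIR498	Down-regulated	183	93.85	3	-1.7145673
31	MIR608	Down-regulated	184	94.36	3	-2.4389162
32	MIR610	Down-regulated	184	94.36	3	-1.9065001
33	MIR564	Down-regulated	185	94.87	3	-2.1568429
34	MIR206	Down-regulated	186	95.38	3	-2.9338987
35	MIR671	Down-regulated	186	95.38	3	-1.6370801
36	MIR297	Down-regulated	188	96.41	3	-2.8914463
37	MIR637	Down-regulated	188	96.41	3	-3.1802687
38	MIR891A	Down-regulated	188	96.41	3	-2.5938886
39	MIR185	Down-regulated	193	98.97	3	-2.8633022
40	MIR183	Up-regulated	176	90.26	4	-1.7540219
41	MIR889	Up-regulated	176	90.26	4	-1.2031172
42	MIR520H	Up-regulated	177	90.77	4	-1.3094348
43	MIR563	Up-regulated	177	90.77	4	-1.8494352
44	MIR433	Up-regulated	178	91.28	4	-1.7722773
45	MIR519D	Up-regulated	178	91.28	4	-1.4657573
46	MIR891B	Up-regulated	179	91.79	4	-2.2433618
47	MIR631	Up-regulated	179	91.79	4	-2.3769263
48	MIR518B	Up-regulated	179	91.79	4	-1.0966398
49	MIR367	Up-regulated	179	91.79	4	-2.0081156
50	MIR613	Up-regulated	180	92.31	4	-1.6223603
51	MIR651	Up-regulated	181	92.82	4	-1.5932408
52	MIR216A	Up-regulated	183	93.85	4	-1.7145673
53	MIR374A	Up-regulated	184	94.36	4	-2.4389162
54	MIR599	Up-regulated	184	94.36	4	-1.9065001
55	MIR577	Up-regulated	185	94.87	4	-2.1568429
56	MIR190B	Up-regulated	186	95.38	4	-2.9338987
57	MIR429	Up-regulated	186	95.38	4	-1.6370801
58	MIR567	Up-regulated	188	96.41	4	-2.8914463
59	MIR618	Up-regulated	188	96.41	4	-3.1802687
60	MIR581	Up-regulated	188	96.41	4	-2.5938886
61	MIR183	Up-regulated	193	98.97	4	-2.8633022
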