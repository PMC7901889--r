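node_id	label	hemisphere	x	y	z
01	OP2-3	left	-65.6	5.9	-17.1
02	24dd	right	46.7	-18.5	-11.5
03	a24pr	left	-8	24.8	-14.7
04	TE2p	right	10.5	-66.9	-35.6
05	SFL	right	38.4	10.9	-49.1
06	STV	right	70.3	-13.5	5.3
07	a47r	left	-28.6	-43.5	-27.5
08	TA2	right	28.1	-54.1	-18
09	a9-46v	left	-35.9	61.5	8.7
10	7Pm	right	20.4	2	26.1
11	47m	right	68.3	14.6	-18.9
12	V3CD	left	-14.7	-7.4	-62.4
13	13l	left	-40.6	-14.9	-22.3
14	A1	right	27.1	49	33.4
15	V3A	left	-35.3	-35	-19.9
16	PGp	right	8.8	52.2	-4.7
17	PeEc	right	36.8	71.9	-1
18	a9-46v	right	3.5	-17.8	42.9
19	TPOJ2	left	-36.9	51.8	14
20	8C	right	27.6	47.1	-25.9
21	p9-46v	right	10	-46.1	15.3
22	9a	right	57.9	9	-26.9
23	TE1a	left	-51.5	2.6	-43
24	TE1m	right	33.3	-42.7	-37.5
25	1	right	22.8	17.8	-0.7
26	POS2	left	-9.8	-40.4	22.8
27	V6A	right	13.4	-14.7	46.6
28	PFt	left	-57.6	40.2	-21.5
29	A4	left	-23.4	32.2	36.1
30	V4t	right	12.3	-45.3	-0.2
31	TGd	right	23.7	38.5	53.7
32	7AL	left	-4.9	38.3	-10.1
33	MIP	left	-17.5	45.4	39.4
34	PoI1	left	-3.3	-3.1	48.9
35	i6-8	right	24	36.6	23.4
36	4	right	5	7.3	-22.8
37	RSC	right	42.5	14.1	-11.2
38	p32	left	-69.6	-0.7	3.2
39	25	left	-27.6	-1.8	26.9
40	IFJp	left	-57.1	4.7	4.3
41	31a	left	-45.5	-9.4	-30.5
42	VMV2	left	-4	-64	-11
43	A4	right	5.4	-10.7	55.4
44	8Ad	left	-11.4	-66	-18.8
45	IP2	left	-11.5	-41.1	-21.7
46	TGd	left	-62.7	32.6	12.8
47	PFop	right	47.7	5.1	-22.3
48	6r	right	35.1	-41.2	19.7
49	6a	left	-20.7	-77.6	8.4
50	TE1a	right	32.5	15.8	-25.8
51	H	right	40.5	44.8	-41.1
52	POS1	left	-38.6	45	-25.3
53	TE2p	left	-49	-1.6	-7.3
54	PeEc	left	-69.2	24.7	7.8
55	10d	right	29.4	-27	3
56	STGa	left	-3.9	62.3	36.1
57	8BL	right	7.2	-0.3	-42
58	PGs	left	-28.4	-52	-37
59	PFm	right	20.9	51.6	45.3
60	OFC	right	30.5	-1.3	-19.8
61	V1	left	-19	-35.7	-31.6
62	6ma	left	-41	-4.6	9.7
63	7AL	right	15.6	41.5	-8.2
64	MI	left	-29.2	-33.9	49.6
65	TE2a	right	36.1	-7.1	-35
66	45	left	-27.8	23	43.9
67	6v	left	-63.3	23.3	20.8
68	VMV1	right	15.6	76.1	5.6
69	LIPd	right	71.4	-2.4	4.2
70	V8	left	-35.7	-4.6	-35.1
71	p32	right	4.3	30.1	-31.4
72	V8	right	41.5	-27.5	15.8
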