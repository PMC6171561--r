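length	bulge	internal
1	3.8	NA
2	2.8	1.7
3	3.2	1.8
4	3.6	1.1
5	4	2
6	4.4	2.3
7	4.57	2.47
8	4.71	2.61
9	4.84	2.74
10	4.95	2.85
11	5.05	2.95
12	5.15	3.05
13	5.24	3.14
14	5.32	3.22
15	5.39	3.29
16	5.46	3.36
17	5.52	3.42
18	5.59	3.49
19	5.64	3.54
20	5.7	3.6
21	5.75	3.65
22	5.8	3.7
23	5.85	3.75
24	5.9	3.8
25	5.94	3.84
26	5.98	3.88
27	6.02	3.92
28	6.06	3.96
29	6.1	4
30	6.14	4.04
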