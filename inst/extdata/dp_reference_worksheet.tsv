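cutoff	fp	fn
10	188	0
13	149	2
14	138	3
15	127	4
16	118	4
17	107	4
18	103	5
20	86	6
21	82	7
22	78	8
25	59	11
26	56	13
27	54	16
30	46	20
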