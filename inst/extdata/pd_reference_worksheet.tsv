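cutoff	fp	fn
10	319	2
13	288	6
14	274	8
15	266	8
20	208	13
21	203	14
22	196	15
30	148	22
32	131	23
33	125	26
34	117	29
40	89	35
41	86	37
42	82	38
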