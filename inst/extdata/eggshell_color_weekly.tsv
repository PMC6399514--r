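week	n	mean	sd	max	min	cv
20	264	53.53	2.8	57.31	48.24	0.0524
25	337	53.86	2.58	60.3	49.63	0.0479
30	313	56.14	3.14	62.32	48.43	0.0559
35	290	56.59	2.93	64.02	49.75	0.0517
40	285	56.95	3.33	64.84	48.37	0.0585
45	319	56.88	4.07	64.38	48.77	0.0716
50	348	58.57	2.97	65.3	51.8	0.0507
55	313	57.79	3.48	65.55	50.43	0.0603
60	184	58.4	3.19	64.34	51.66	0.0546
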