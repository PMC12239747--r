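gene_id	amplicon_size	base_changes	g_to_a	c_to_t	other	missense	nonsense	silent
Glyma.02G240400	5600	114	41	41	32	66	3	32
Glyma.03G216300	6241	117	37	51	29	72	6	39
Glyma.09G073600	6397	122	39	55	28	76	4	42
Glyma.09G167000	5901	95	33	37	25	60	8	27
Glyma.13G114000	5528	82	33	42	7	50	2	30
Glyma.14G209900	5789	114	60	35	19	78	6	30
Glyma.15G151000	10938	109	41	46	22	72	5	32
Glyma.16G217200	5611	119	41	48	30	83	8	28
Glyma.17G045800	5574	139	67	58	14	88	5	46
Glyma.19G212800	6134	97	31	41	25	68	6	23
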