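gene_id	gene_length	cds_length	exon_count	protein_length	pI	mol_wt
Glyma.02G240400	5600	2523	14	841	6.81	95.33
Glyma.03G216300	6241	2439	15	813	5.76	92.31
Glyma.09G073600	6397	2433	12	811	6.02	93.66
Glyma.09G167000	5901	2766	15	922	6.91	105.38
Glyma.13G114000	5528	2418	12	806	6.04	92.24
Glyma.14G209900	5789	2523	14	841	6.01	86.86
Glyma.15G182600	6296	2421	13	807	5.87	92.72
Glyma.15G151000	10938	2409	15	803	5.84	91.57
Glyma.16G217200	5611	2763	15	921	6.66	103.91
Glyma.17G045800	5574	2418	12	806	6.34	96.1
Glyma.19G212800	6134	2439	15	813	5.95	92.26
Glyma.11G212700	5184	2538	15	846	6.53	95.77
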