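dataset_id	version	n_genes	n_samples	go_score	codon_score	reproducibility_score
Ath-m	c6.0	20836	15275	7.08	2.29	2.57
Ath-m	c5.0	20836	11171	7.02	2.24	2.55
Ath-m	c4.1	20906	1388	5.48	1.56	2.08
Ath-m	c4.0	20906	1388	5.06	1.59	1.82
Ath-m	c3.1	20703	771	4.96	1.46	2.14
Ath-m	c3.0	22263	771	4.96	1.46	2.10
Ath-r	c2.0	25296	1401	4.81	1.67	2.20
Ath-r	c1.0	25838	328	4.27	1.59	1.67
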