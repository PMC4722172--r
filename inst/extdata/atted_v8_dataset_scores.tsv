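dataset_id	species	version	n_genes	n_samples	codon_score	reproducibility_score
Ath-m	Arabidopsis thaliana	c6.0	20836	15275	2.29	2.57
Ath-r	Arabidopsis thaliana	c2.0	25296	1401	1.67	2.20
Bra-r	Brassica rapa	c1.0	35431	257	1.63	1.25
Gma-m	Glycine max	c2.0	15902	1115	1.63	1.61
Gma-r	Glycine max	c1.0	42787	410	1.73	1.48
Mtr-m	Medicago truncatula	c2.0	6226	909	1.08	NA
Osa-m	Oryza sativa	c5.0	20625	2098	1.59	1.79
Osa-r	Oryza sativa	c1.0	17548	222	1.49	1.64
Ppo-m	Populus trichocarpa	c1.0	21909	404	1.29	1.59
Sly-m	Solanum lycopersicum	c1.0	5786	401	1.07	1.51
Sly-r	Solanum lycopersicum	c1.0	23195	288	1.34	1.27
Vvi-m	Vitis vinifera	c2.0	9564	245	1.18	1.32
Zma-m	Zea mays	c2.0	11069	755	1.62	1.94
Zma-r	Zea mays	c1.0	22592	1571	2.55	1.85
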