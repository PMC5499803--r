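species	clade1	clade2	clade3	clade4	total
Lolium_perenne	0	25	0	0	25
Triticum_urartu	4	9	0	7	20
Hordeum_vulgare	0	6	0	1	7
Setaria_italica	8	0	0	5	13
Oryza_sativa	0	2	0	10	12
Sorghum_bicolor	1	0	0	17	18
Zea_mays	7	0	0	2	9
Brachypodium_distachyon	0	9	0	0	9
Arabidopsis_thaliana	0	0	28	0	28
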