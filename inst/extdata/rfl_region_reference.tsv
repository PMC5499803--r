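clade	species	chrom	start	end	n_genes
1	Setaria_italica	Ch8	29882484	31204264	5
1	Zea_mays	Ch2	227716868	228633247	6
1	Setaria_italica	Ch7	15683154	15692828	2
2	Oryza_sativa	Ch4	16684906	16757223	2
2	Hordeum_vulgare	Ch1	47176692	50263441	3
2	Brachypodium_distachyon	Ch2	38479458	39012768	7
3	Arabidopsis_thaliana	Ch1	4183066	4355929	4
3	Arabidopsis_thaliana	Ch1	23176930	23988740	17
4	Sorghum_bicolor	Ch2	5169697	5744703	3
4	Zea_mays	Ch8	76606724	76690742	2
4	Sorghum_bicolor	Ch5	2222303	2776884	9
4	Oryza_sativa	Ch10	18823675	19143586	6
4	Oryza_sativa	Ch8	374091	383986	2
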