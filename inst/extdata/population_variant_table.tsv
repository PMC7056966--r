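class	sites	snps	snps_per_site	snp_maf	indels	indels_per_site	indel_maf
Protein Coding	31264	41	0.0013	0.0206	0	0.0000	NA
Nonsynonymous	24323	22	0.0009	0.0244	0	0.0000	NA
Synonymous	6941	19	0.0027	0.0163	0	0.0000	NA
rRNA	5222	3	0.0006	0.0010	0	0.0000	NA
tRNA	1689	0	0.0000	NA	0	0.0000	NA
Pseudogene	1256	5	0.0040	0.0025	0	0.0000	NA
Intron	35335	72	0.0020	0.0218	18	0.0005	0.0116
Intergenic	293042	987	0.0034	0.0263	172	0.0006	0.0239
Total	367808	1108	0.0030	0.0256	190	0.0005	0.0006
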