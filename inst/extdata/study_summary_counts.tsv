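key	value
degs_nat_vs_n_prefilter	650
sex_genes_total	52
sex_genes_y	22
sex_genes_x	7
sex_genes_autosomal	23
sex_genes_overlapping_degs	4
degs_nat_vs_n_final	646
coding_degs	273
coding_degs_up	131
coding_degs_down	142
pattern_up-up	38
pattern_up-stable	354
pattern_up-down	37
pattern_down-down	31
pattern_down-stable	148
pattern_down-up	38
biotype_pseudogene	244
biotype_lincRNA	26
biotype_snRNA	20
biotype_snoRNA	17
biotype_antisense	20
biotype_processed_transcript	14
biotype_sense_intronic	11
biotype_misc_RNA	11
biotype_scaRNA	5
biotype_sense_overlapping	2
biotype_TEC	2
biotype_retained_intron	1
lt_reference_genes_in_universe	456
lt_reference_genes_overlapping	440
degs_nat_ltneg_vs_n	632
common_degs_nat_and_ltneg	474
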