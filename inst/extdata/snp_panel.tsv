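snp_id	chr	gene	location	effect_allele	other_allele
rs12027135	1	TMEM57	intron	A	T
rs2131925	1	ANGPTL3/DOCK7	intron	G	T
rs2479409	1	PCSK9	nearGene-5	G	A
rs4660293	1	PABPC4	intron	G	A
rs673548	2	APOB	intron	A	G
rs4731702	7	KLF14	intergenic	T	C
rs10503669	8	LPL	intergenic	A	C
rs12272004	11	APOA	intergenic	A	C
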