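line_id	variant_id	type	chrom	pos	ref	alt	gt	dp	ad	status	sanger_confirmed
M149	149_IND1	indel	1	23789397	GAT	G	hom_alt	34	34	unique	Y
M153	153_IND4	indel	4	15522985	C	CTCAGCCG	hom_alt	29	29	unique	Y
M166	166_IND1	indel	1	18131046	AGCGCATGTGCCATG	A	hom_alt	31	30	unique	Y
M166	166_IND3	indel	6	5694121	CA	C	het	36	19	unique	Y
M193	193_SNP1	SNP	2	32736082	A	ACCAACG	hom_alt	27	27	unique	Y
M193	193_SNP4	SNP	6	28952090	A	G	hom_alt	38	37	unique	Y
M193	193_SNP5	SNP	7	10033642	T	C	het	30	14	unique	Y
M193	193_SNP6	SNP	12	24819926	C	A	het	29	3	allele_ratio	N
M193	193_IND6	indel	12	1851681	AC	A	hom_alt	25	25	unique	Y
M225	225_SNP2	SNP	3	30121299	T	G	hom_alt	41	41	unique	Y
M225	225_SNP3	SNP	5	18773517	G	A	hom_alt	33	32	not_unique	Y
M232	232_IND1	indel	1	38864179	AGG	A	hom_alt	28	28	unique	Y
M238	238_SNP4	SNP	8	24636417	G	A	het	32	17	unique	Y
M238	238_SNP5	SNP	9	19013812	G	C	hom_alt	30	30	unique	Y
M238	238_IND1	indel	1	2382470	CG	C	hom_alt	26	26	unique	Y
M238	238_IND2	indel	1	3324566	GGTGGT	G	hom_alt	35	34	unique	Y
M238	238_IND4	indel	6	12475810	C	CAAGT	het	28	13	unique	Y
M238	238_IND5	indel	6	16993055	TA	A	hom_alt	37	37	unique	Y
M238	238_IND6	indel	6	17139752	A	AGATGCTCTAGGACAGTTTGTTGG	hom_alt	24	23	not_unique	Y
M242	242_SNP1	SNP	1	14877967	G	T	hom_alt	39	39	not_unique	Y
M242	242_SNP3	SNP	3	8704769	G	A	hom_alt	31	31	not_unique	Y
M242	242_SNP5	SNP	8	8951950	G	T	het	34	16	unique	Y
M242	242_IND1	indel	1	13935043	A	AT	het	12	5	low_coverage	N
M242	242_IND4	indel	7	29013042	CAAGG	C	hom_alt	29	29	unique	Y
M242	242_IND4b	indel	7	29013050	G	GC	hom_alt	29	28	unique	Y
M244	244_SNP3	SNP	7	11432559	C	T	het	21	2	allele_ratio	N
M244	244_SNP4	SNP	11	22433103	C	T	het	25	2	allele_ratio	N
M244	244_IND1	indel	8	24737886	A	ACCAACG	hom_alt	36	36	not_unique	Y
M314	314_SNP2	SNP	4	28342904	G	T	hom_alt	30	30	unique	Y
M314	314_IND1	indel	4	3682688	G	GAT	het	33	15	unique	Y
M314	314_IND1b	indel	4	3682689	G	GA	het	33	14	not_unique	Y
M314	314_IND1c	indel	4	3682697	GGT	G	het	31	16	unique	Y
M314	314_IND1d	indel	4	3682701	CAG	C	het	31	15	unique	Y
M314	314_IND2	indel	7	15991122	AC	A	hom_alt	27	27	unique	Y
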