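variant_id	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n	trait	source
rs0002	2	2000	A	G	0.32	0.017	0.015	0.2570742986848299	153781	birth_weight	synthetic
rs0003	3	3000	T	C	0.55	-0.018	0.015	0.23013934044341655	153781	birth_weight	synthetic
rs0004	4	4000	T	G	0.4	0.013	0.015	0.38612467428381386	153781	birth_weight	synthetic
rs0005	5	5000	T	A	0.8	-0.011	0.015	0.46335514926959653	153781	birth_weight	synthetic
rs0006	6	6000	A	G	0.31	0.005	0.015	0.7388826803635272	153781	birth_weight	synthetic
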