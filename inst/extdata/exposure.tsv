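variant_id	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n	trait	source
rs0001	1	1000	A	G	0.3	0.1	0.008	7.465128597755428e-36	224459	WHRadjBMI	synthetic
rs0002	2	2000	A	G	0.32	0.09	0.008	2.3159206371372835e-29	224459	WHRadjBMI	synthetic
rs0003	3	3000	C	T	0.45	0.08	0.008	1.5239706048321054e-23	224459	WHRadjBMI	synthetic
rs0004	4	4000	A	C	0.4	0.07	0.008	2.1335274750949717e-18	224459	WHRadjBMI	synthetic
rs0005	5	5000	A	T	0.2	0.06	0.008	6.381783345821793e-14	224459	WHRadjBMI	synthetic
rs0006	6	6000	A	G	0.31	0.03	0.008	1.7683457040160776e-4	224459	WHRadjBMI	synthetic
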