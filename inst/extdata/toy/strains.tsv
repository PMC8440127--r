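strain_id	genus	species	sugar_utilization	growth_15C	growth_45C	oxygen_class	genome_size	n_cds	n_hgt_cds	gc_content	n_rrna	n_trna	n_crispr	isolation_source
a1	Lactobacillus	lactobacillus_sp1	1	no	no	microaerobic	2010000	2010	28	0.36	4	55	0	dairy
a2	Lactobacillus	lactobacillus_sp2	2	no	no	obligate_anaerobic	2020000	2020	36	0.37	5	60	1	vegetable
a3	Lactobacillus	lactobacillus_sp3	8	yes	no	facultatively_anaerobic	2080000	2080	84	0.38	6	65	2	brewing
a4	Lactobacillus	lactobacillus_sp4	7	yes	no		2070000	2070	76	0.39	4	70	0	dairy
a5	Lactobacillus	lactobacillus_sp5	10	yes	yes	facultatively_anaerobic	2100000	2100	100	0.4	5	55	1	vegetable
a6	Lactobacillus	lactobacillus_sp6	14	yes	yes	facultatively_anaerobic	2140000	2140	132	0.41	6	60	2	brewing
b1	Lacticaseibacillus	lacticaseibacillus_sp1	15	yes	yes	facultatively_anaerobic	2150000	2150	140	0.42	4	65	0	dairy
b2	Lacticaseibacillus	lacticaseibacillus_sp2	12	yes	no	facultatively_anaerobic	2120000	2120	116	0.43	5	70	1	vegetable
b3	Lacticaseibacillus	lacticaseibacillus_sp3	16	yes	yes	facultatively_anaerobic	2160000	2160	148	0.44	6	55	2	brewing
b4	Lacticaseibacillus	lacticaseibacillus_sp4	1	no	no	facultatively_anaerobic	2010000	2010	28	0.45	4	60	0	dairy
b5	Lacticaseibacillus	lacticaseibacillus_sp5	2	no	no	obligate_anaerobic	2020000	2020	36	0.46	5	65	1	vegetable
b6	Lacticaseibacillus	lacticaseibacillus_sp6	9	yes		facultatively_anaerobic	2090000	2090	92	0.47	6	70	2	brewing
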