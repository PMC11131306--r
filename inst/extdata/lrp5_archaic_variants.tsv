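chrom	pos	ref	alt	protein_change	residue	gnomad_frequency	sift	polyphen	carriers	hbm_residue	base_quality	alignment_quality	phylop	in_domain	ddg_kcal_mol
11	68115422	G	A	p.A67T	67	7.08e-06	0.0256	1.000	Vi33.26	FALSE	30	200	2.5	TRUE	0.91
11	68115423	C	T	p.A67V	67	NA	0.001	1.000	Vi33.16	FALSE	30	200	2.5	TRUE	5.77
11	68125186	G	A	p.R186Q	186	4.60e-05	0.000	1.000	Vi33.16,Vi33.25	FALSE	30	200	3.1	TRUE	NA
11	68131373	T	G	p.M282R	282	NA	0.039	0.999	Mez1	TRUE	30	200	2.8	TRUE	6.16
11	68131400	G	A	p.R291Q	291	1.22e-05	0.012	0.995	Denisovan	FALSE	30	200	2.6	TRUE	NA
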