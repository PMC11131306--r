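chrom	pos	ref	alt	protein_change	residue	gnomad_frequency	sift	polyphen	carriers	hbm_residue	base_quality	alignment_quality	phylop	in_domain	ddg_kcal_mol
11	68120001	G	A	p.D111N	111	NA	0.010	0.990	Vi33.26	FALSE	15	200	2.5	TRUE	NA
11	68121002	C	T	p.S127F	127	NA	0.010	0.990	Vi33.26	FALSE	30	90	2.5	TRUE	NA
11	68124003	C	T	p.T173I	173	NA	0.400	0.990	Vi33.16	FALSE	30	200	2.5	TRUE	NA
11	68126004	G	A	p.E204K	204	NA	0.010	0.300	Mez1	FALSE	30	200	2.5	TRUE	NA
11	68129005	G	A	p.V260M	260	NA	0.010	0.990	Denisovan	FALSE	30	200	0.5	TRUE	NA
11	68190006	G	T	p.Q1500H	1500	NA	0.010	0.990	Vi33.25	FALSE	30	200	2.5	FALSE	NA
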