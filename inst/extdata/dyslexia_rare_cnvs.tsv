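# curated rare-CNV call set for a 322-proband dyslexia cohort (1-based starts, size = end - start)
chrom	start	end	size	band	type	sample	cohort	hotspot_class	gene_count	inheritance	control_count
chr1	144106777	144451305	344528	1q21.1	deletion	2602	dyslexia	HS	1	NA	2
chr3	139732796	140171095	438299	3q22.3	duplication	1806	dyslexia	non_HS	142	NA	1
chr6	65179840	66364033	1184193	6q12	deletion	2803	dyslexia	non_HS	1	paternal	1
chr4	123017758	123458923	441165	4q27	duplication	2286	dyslexia	non_HS	0	maternal	0
chr7	40606348	40819984	213636	7p14.1	deletion	2244	dyslexia	non_HS	1	maternal	0
chr7	68820751	68904999	84248	7q11.22	deletion	2867	dyslexia	HS	2	paternal	0
chr7	69876932	70546042	669110	7q11.22	duplication	1102	dyslexia	HS	1	paternal	0
chr7	110381300	110851860	470560	7q31.1	deletion	3437	dyslexia	non_HS	102	paternal	2
chr8	11373083	11434911	61828	8p23.1	deletion	1012	dyslexia	HS	16	maternal	0
chr9	6348644	6740836	392192	9p24.1	deletion	1004	dyslexia	non_HS	11	paternal	0
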