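chrom	start	end	gene	reason	whole_gene
6	170561916	170561960	TBP	G/S repeat of population-variable length; printed end coordinate corrected to make the interval well-formed	FALSE
9	12775850	12775885	LURAP1L	Q repeat of population-variable length	FALSE
17	NA	NA	KRTAP4-5	~26 pentameric amino-acid repeats, copy number varies between individuals; masked as a whole gene	TRUE
13	45596547	45596602	ERICH6B	in-frame deletions frequent in European populations, missed by automatic filters	FALSE
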