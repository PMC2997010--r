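# synthetic partner genome of toy_genome_a.tsv; gene 6 strand-flipped
gene_id	chrom	start	end	strand
GB_g01	chrIII	2000	4999	+
GB_g02	chrIII	7000	9999	+
GB_g03	chrIII	12000	14999	-
GB_g04	chrIII	17000	19999	+
GB_g05	chrIII	22000	24999	+
GB_g06	chrIII	27000	29999	-
GB_g07	chrIII	32000	34999	-
GB_g08	chrIII	37000	39999	+
GB_g09	chrIII	42000	44999	+
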