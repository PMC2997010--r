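# synthetic 9-gene instance: one-to-one orthologs in identical order,
# ortholog of gene 6 strand-inverted in the partner genome
gene_id	chrom	start	end	strand
GA_g01	chrIII	1000	3999	+
GA_g02	chrIII	6000	8999	+
GA_g03	chrIII	11000	13999	-
GA_g04	chrIII	16000	18999	+
GA_g05	chrIII	21000	23999	+
GA_g06	chrIII	26000	28999	+
GA_g07	chrIII	31000	33999	-
GA_g08	chrIII	36000	38999	+
GA_g09	chrIII	41000	43999	+
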