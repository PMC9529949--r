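gene_id	gene_name	chrom	start	end	strand	biotype
GA	ALPHA	chr1	50000	52000	+	protein_coding
GB	BETA	chr1	150000	152000	-	lncRNA
GC	GAMMA	chr1	400000	402000	+	protein_coding
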