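genome_id	gene_id	ordinal	functional_class	glyco_flag_override
cotonvirus	ORF_707	1	helicase	
cotonvirus	ORF_708	2	dehydratase	
cotonvirus	ORF_709	3	reductase	
cotonvirus	ORF_710	4	epimerase	
cotonvirus	ORF_711	5	glycosyltransferase	
cotonvirus	ORF_712	6	glycosyltransferase	
cotonvirus	ORF_713	7	glycosyltransferase	
cotonvirus	ORF_714	8	permease	
cotonvirus	ORF_715	9	thioredoxin_like	
cotonvirus	ORF_716	10	hypothetical	
cotonvirus	ORF_717	11	glycosyltransferase	
cotonvirus	ORF_718	12	epimerase	
cotonvirus	ORF_719	13	acetyltransferase	
cotonvirus	ORF_720	14	aminotransferase	
cotonvirus	ORF_721	15	papain_like	
cotonvirus	ORF_722	16	glycosyltransferase	
cotonvirus	ORF_723	17	papain_like	
cotonvirus	ORF_724	18	sulfotransferase	
cotonvirus	ORF_725	19	sulfate_kinase	
cotonvirus	ORF_726	20	muts	
cotonvirus	ORF_727	21	rna_polymerase	
cotonvirus	ORF_728	22	glycosyltransferase	
cotonvirus	ORF_729	23	hypothetical	
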