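genome_id	gene_id	ordinal	functional_class	glyco_flag_override
moumouvirus_maliensis	mm416	1	helicase	
moumouvirus_maliensis	mm417	2	glycosyltransferase	
moumouvirus_maliensis	mm418	3	glycosyltransferase	
moumouvirus_maliensis	mm419	4	reductase	
moumouvirus_maliensis	mm420	5	glycosyltransferase	
moumouvirus_maliensis	mm421	6	reductase	
moumouvirus_maliensis	mm422	7	dehydratase	
moumouvirus_maliensis	mm423	8	thioredoxin_like	
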