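genome_id	gene_id	ordinal	functional_class	glyco_flag_override
moumouvirus_australiensis	ma456	1	helicase	
moumouvirus_australiensis	ma457	2	sulfate_kinase	
moumouvirus_australiensis	ma458	3	dehydratase	
moumouvirus_australiensis	ma459	4	reductase	
moumouvirus_australiensis	ma460	5	epimerase	
moumouvirus_australiensis	ma461	6	sulfotransferase	
moumouvirus_australiensis	ma462	7	papain_like	
moumouvirus_australiensis	ma463	8	glycosyltransferase	
moumouvirus_australiensis	ma464	9	papain_like	
moumouvirus_australiensis	ma465	10	aminotransferase	
moumouvirus_australiensis	ma466	11	acetyltransferase	
moumouvirus_australiensis	ma467	12	dehydratase	
moumouvirus_australiensis	ma468	13	glycosyltransferase	
moumouvirus_australiensis	ma469	14	thioredoxin_like	
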