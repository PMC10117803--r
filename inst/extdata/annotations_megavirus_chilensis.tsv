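genome_id	gene_id	ordinal	functional_class	glyco_flag_override
megavirus_chilensis	mg533	1	helicase	
megavirus_chilensis	mg534	2	dehydratase	
megavirus_chilensis	mg535	3	reductase	
megavirus_chilensis	mg536	4	epimerase	
megavirus_chilensis	mg537	5	glycosyltransferase	
megavirus_chilensis	mg538	6	pyruvyltransferase	
megavirus_chilensis	mg539	7	glycosyltransferase	
megavirus_chilensis	mg540	8	thioredoxin_like	
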