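genome_id	gene_id	ordinal	functional_class	glyco_flag_override
mimivirus	R131	1	transcription_factor	
mimivirus	R132	2	methyltransferase	
mimivirus	R133	3	hypothetical	
mimivirus	L134	4	hypothetical	
mimivirus	R135	5	oxidoreductase	
mimivirus	L136	6	aminotransferase	
mimivirus	L137	7	glycosyltransferase	
mimivirus	L138	8	glycosyltransferase	
mimivirus	R139	9	glycosyltransferase	
mimivirus	L140	10	glycosyltransferase	
mimivirus	R141	11	dehydratase	
mimivirus	L142	12	acetyltransferase	
mimivirus	L143	13	pyruvyltransferase	
mimivirus	L144	14	hypothetical	
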