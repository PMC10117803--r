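genome_id	gene_id	ordinal	functional_class	glyco_flag_override
tupanvirus_deep_ocean	R496	1	glycosyltransferase	
tupanvirus_deep_ocean	R497	2	hypothetical	
tupanvirus_deep_ocean	L498	3	glycosyltransferase	
tupanvirus_deep_ocean	R499	4	sulfate_kinase	
tupanvirus_deep_ocean	R500	5	hypothetical	
tupanvirus_deep_ocean	R501	6	glycosyltransferase	
tupanvirus_deep_ocean	L502	7	glycosyltransferase	
tupanvirus_deep_ocean	R503	8	glycosyltransferase	
tupanvirus_deep_ocean	R504	9	glycosyltransferase	
tupanvirus_deep_ocean	L505	10	glycosyltransferase	
tupanvirus_deep_ocean	L506	11	methyltransferase	
tupanvirus_deep_ocean	R507	12	glycosyltransferase	
tupanvirus_deep_ocean	L508	13	glycosyltransferase	
tupanvirus_deep_ocean	L509	14	aminotransferase	
tupanvirus_deep_ocean	L510	15	glycosyltransferase	
tupanvirus_deep_ocean	L511	16	glycosyltransferase	
tupanvirus_deep_ocean	L512	17	glycosyltransferase	
tupanvirus_deep_ocean	R513	18	glycosyltransferase	
tupanvirus_deep_ocean	L514	19	acetyltransferase	
tupanvirus_deep_ocean	L515	20	epimerase	
tupanvirus_deep_ocean	R516	21	glycosyltransferase	
tupanvirus_deep_ocean	L517	22	methyltransferase	
tupanvirus_deep_ocean	L518	23	reductase	
tupanvirus_deep_ocean	R519	24	glycosyltransferase	
tupanvirus_deep_ocean	R520	25	oxidoreductase	TRUE
tupanvirus_deep_ocean	L521	26	trna_synthetase	
tupanvirus_deep_ocean	R522	27	hypothetical	
tupanvirus_deep_ocean	L523	28	trna_synthetase	
tupanvirus_deep_ocean	R524	29	hypothetical	
tupanvirus_deep_ocean	L525	30	hypothetical	
tupanvirus_deep_ocean	L526	31	hypothetical	
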