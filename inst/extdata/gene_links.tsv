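snp_id	gene_symbol	ensembl_id	regulation_type
rs9494257	BCLAF1	ENSG00000029363	distal transcriptional regulation
rs9494257	AHI1	ENSG00000135541	distal transcriptional regulation
rs9494257	LINC00271	ENSG00000231028	distal transcriptional regulation
rs6903949	MYB	ENSG00000118513	distal transcriptional regulation
rs6903949	BCLAF1	ENSG00000029363	distal transcriptional regulation
rs6903949	AHI1	ENSG00000135541	distal transcriptional regulation
rs6903949	LINC00271	ENSG00000231028	distal transcriptional regulation
rs6996881	ZNF703	ENSG00000183779	distal transcriptional regulation
rs6996881	ERLIN2	ENSG00000147475	distal transcriptional regulation
rs6996881		ENSG00000183154	distal transcriptional regulation
rs6996881		ENSG00000253161	distal transcriptional regulation
rs4739519	ZNF703	ENSG00000183779	distal transcriptional regulation
rs4739519		ENSG00000254290	distal transcriptional regulation
rs6988263	ZNF703	ENSG00000183779	distal transcriptional regulation
rs6988263		ENSG00000254290	distal transcriptional regulation
rs12156293	ZNF703	ENSG00000183779	distal transcriptional regulation
rs12156293		ENSG00000254290	distal transcriptional regulation
rs12156293	ERLIN2	ENSG00000147475	distal transcriptional regulation
rs12156293		ENSG00000183154	distal transcriptional regulation
rs1568658		ENSG00000228421	distal transcriptional regulation
rs1568658	TRIL	ENSG00000176734	distal transcriptional regulation
rs1568658		ENSG00000255690	distal transcriptional regulation
rs5994449	DEPDC5	ENSG00000100150	distal transcriptional regulation
rs5994449	FBXO7	ENSG00000100225	distal transcriptional regulation
rs5994449	SYN3	ENSG00000185666	distal transcriptional regulation
rs5994449	PRR14L	ENSG00000183530	distal transcriptional regulation
rs5994449	PISD	ENSG00000241878	distal transcriptional regulation
rs5994449	EIF4ENIF1	ENSG00000184708	distal transcriptional regulation
rs5994449	RNU6-28	ENSG00000199248	distal transcriptional regulation
rs5994449	SFI1	ENSG00000198089	distal transcriptional regulation
rs5753816	YWHAH	ENSG00000128245	distal transcriptional regulation
rs5753816	C22orf24	ENSG00000128254	distal transcriptional regulation
rs5753816	PISD	ENSG00000241878	distal transcriptional regulation
rs5753816	DEPDC5	ENSG00000100150	distal transcriptional regulation
rs5753816	RNU6-28	ENSG00000199248	distal transcriptional regulation
rs5753816	SFI1	ENSG00000198089	distal transcriptional regulation
rs5753816	EIF4ENIF1	ENSG00000184708	distal transcriptional regulation
rs5753816	RFPL3S	ENSG00000205853	distal transcriptional regulation
rs5753816		ENSG00000230736	distal transcriptional regulation
rs5753816		ENSG00000243519	distal transcriptional regulation
rs5753816		ENSG00000241954	distal transcriptional regulation
rs5753816		ENSG00000232218	distal transcriptional regulation
rs5753816	SYN3	ENSG00000185666	distal transcriptional regulation
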