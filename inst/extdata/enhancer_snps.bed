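chr1	10291873	10291874	rs12751375	0	+	CHB
chr1	10306037	10306038	rs6700866	0	+	CHB
chr6	135827471	135827472	rs9494257	0	+	CHB
chr6	135680137	135680138	rs17064474	0	+	CHB
chr6	135748923	135748924	rs17721919	0	+	CHB
chr6	135749377	135749378	rs17721931	0	+	CHB
chr6	135821065	135821066	rs6903949	0	+	CHB
chr8	37407919	37407920	rs6996881	0	+	CHB
chr8	37412858	37412859	rs4739519	0	+	CHB
chr8	37414659	37414660	rs6988263	0	+	CHB
chr8	37419921	37419922	rs12156293	0	+	CHB
chr6	31410523	31410524	rs6928810	0	+	JPT
chr6	31410947	31410948	rs3869132	0	-	JPT
chr6	31354594	31354595	rs2596562	0	-	JPT
chr6	31361709	31361710	rs2523475	0	-	JPT
chr6	31362929	31362930	rs2523467	0	-	JPT
chr6	31364458	31364459	rs9501387	0	+	JPT
chr7	29141557	29141558	rs1568658	0	-	JPT
chr16	12625394	12625395	rs1794304	0	+	JPT
chr22	32304178	32304179	rs5994449	0	+	JPT
chr22	32312841	32312842	rs5753816	0	+	JPT
chr22	32315734	32315735	rs5749339	0	+	JPT
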