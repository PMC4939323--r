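snp_id	p_value	chrom	population	pmid
rs17401966	1.2e-19	chr1	CHB	20676096
rs1249458	8.3e-06	chr2	CHB	22807686
rs1714259	1.1e-06	chr2	CHB	22807686
rs2396470	5.1e-07	chr2	CHB	20676096
rs7424161	8.8e-06	chr2	CHB	22807686
rs7574865	1.7e-11	chr2	CHB	23242368
rs3905886	3.7e-06	chr3	CHB	22807686
rs1073547	6.8e-06	chr4	CHB	22807686
rs17081345	3.7e-07	chr6	CHB	20676096
rs9272105	3.3e-23	chr6	CHB	22807686
rs9275319	8.7e-19	chr6	CHB	23242368
rs9494257	1.1e-14	chr6	CHB	20676096
rs12682266	6.7e-06	chr8	CHB	22174901
rs1573266	7.4e-06	chr8	CHB	22174901
rs2275959	6.4e-06	chr8	CHB	22174901
rs7821974	7.0e-06	chr8	CHB	22174901
rs7898005	7.0e-08	chr10	CHB	20676096
rs10160758	6.0e-06	chr11	CHB	22807686
rs10896464	6.5e-06	chr11	CHB	22807686
rs2611145	9.3e-06	chr11	CHB	22174901
rs3825023	3.1e-06	chr11	CHB	22807686
rs7119426	3.5e-06	chr11	CHB	22807686
rs402071	8.6e-06	chr19	CHB	22807686
rs3092194	4.4e-06	chr20	CHB	22807686
rs368007	9.9e-06	chr20	CHB	22807686
rs455804	4.4e-10	chr21	CHB	22807686
rs1980215	2.3e-06	chr3	JPT	21499248
rs2596542	4.2e-13	chr6	JPT	21499248
rs9275572	1.4e-09	chr6	JPT	21499248
rs1568658	6.9e-06	chr7	JPT	21499248
rs952656	2.8e-06	chr8	JPT	21499248
rs4363614	4.2e-07	chr11	JPT	21499248
rs1957496	4.6e-06	chr14	JPT	21499248
rs8019534	3.9e-06	chr14	JPT	21499248
rs1794304	3.6e-06	chr16	JPT	21725309
rs2208456	3.8e-06	chr20	JPT	21499248
rs1012068	1.3e-14	chr22	JPT	21725309
rs11703779	4.2e-06	chr22	JPT	21725309
rs4820994	3.0e-06	chr22	JPT	21725309
rs4820996	4.2e-06	chr22	JPT	21725309
rs5753816	4.9e-06	chr22	JPT	21725309
rs5753818	9.4e-06	chr22	JPT	21725309
rs5998152	1.2e-07	chr22	JPT	21725309
rs7287054	3.8e-06	chr22	JPT	21725309
rs737084	5.9e-06	chr22	JPT	21725309
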