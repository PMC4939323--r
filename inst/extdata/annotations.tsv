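snp_id	is_regulatory	is_distal	chromatin_states	regulatory_elements
rs12751375	yes	no	Inactive region	n/a
rs6700866	yes	no	Weak transcription; ZNF genes and repeats; strong transcription; enhancers	n/a
rs9494257	yes	yes	Enhancers; flanking active TSS; weak transcription	Chromatin interactive region
rs17064474	yes	no	Weak transcription; active TSS; flanking active TSS; enhancers	n/a
rs17721919	yes	no	Weak transcription	n/a
rs17721931	yes	no	Weak transcription	n/a
rs6903949	yes	yes	Weak transcription; enhancers	TF binding region; chromatin interactive region
rs6996881	yes	yes	Weak transcription; enhancers	Chromatin interactive region
rs4739519	yes	yes	Enhancers; weak transcription	Chromatin interactive region
rs6988263	yes	yes	Enhancers; weak transcription; genic enhancers; bivalent enhancer; flanking active TSS	Chromatin interactive region
rs12156293	yes	yes	Enhancers; weak transcription; bivalent enhancer; genic enhancers	Chromatin interactive region
rs1568658	yes	yes	Weak transcription; enhancers; strong transcription	Chromatin interactive region
rs5994449	yes	yes	Weak transcription; strong transcription; ZNF genes and repeats	Chromatin interactive region
rs5753816	yes	yes	Weak transcription; enhancers; flanking active TSS	Chromatin interactive region
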