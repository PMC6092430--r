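gene	hgvs_p	allele	wt_peptide	wt_ic50_nM	mut_peptide	mut_ic50_nM	tcr_call
MSH6	p.F1088LfsX5	HLA-A*02:06	LLPEDTPPF	71.02	LLPEDTPPL	8.61	Deprioritized
PIGO	p.T788LfsX25	HLA-A*02:06	QADLDYVVP	32787.64	KLTWIMWSL	10.3	High
AXIN2	p.G665AfsX24	HLA-A*02:06	HLWGGNSGH	12860.25	HLWGATAGT	425.67	High
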