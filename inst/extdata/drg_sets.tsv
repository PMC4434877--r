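comparison	gene
mdd_pre_vs_control	FOSL1
mdd_pre_vs_control	FOXL1
mdd_pre_vs_control	MEF2A
mdd_pre_vs_control	HNF1A
mdd_pre_vs_control	IRF1
mdd_pre_vs_control	JUN
mdd_pre_vs_control	SOX9
mdd_pre_vs_control	SRF
mdd_pre_vs_control	TFAP4
mdd_pre_vs_control	TFCP2
mdd_pre_vs_control	TLX2
mdd_pre_vs_control	HLF
mdd_pre_vs_control	ZNF423
mdd_post_vs_control	BPTF
mdd_post_vs_control	EP300
mdd_post_vs_control	FOXI1
mdd_post_vs_control	IL10
mdd_post_vs_control	NFKB1
mdd_post_vs_control	NFYC
mdd_post_vs_control	NR3C1
mdd_post_vs_control	TP53
mdd_post_vs_control	USF2
mdd_post_vs_control	FOXL1
ssd_pre_vs_control	FOSB
ssd_pre_vs_control	PATZ1
ssd_pre_vs_control	TFAP4
ssd_post_vs_control	EGR1
ssd_post_vs_control	IRF1
ssd_post_vs_control	MYOD1
ssd_post_vs_control	SOX5
ssd_post_vs_control	TFAP4
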