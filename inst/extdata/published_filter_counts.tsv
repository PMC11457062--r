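step	n_retained
raw_snp_variants	1363731
gatk_hard_filter	1189068
final_retained	1127943
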