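population	n	mean_het_variants	mean_hom_alt_variants
CHT	10	180943.2	116275.7
HOO	5	126719.8	84774.6
PAL	4	58128.5	101464.5
CHA	1	74996.0	31385.0
CAS	1	14552.0	96.0
WHI	6	49401.8	18524.8
SLA	11	64393.5	19442.5
HCK	9	67943.5	24188.0
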