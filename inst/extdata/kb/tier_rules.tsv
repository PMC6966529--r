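gene	change	condition	tier_if_true	tier_if_false
EGFR	L747P	co_occurring_cpv_same_gene	I	III
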