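region_class	tandem_bases	all_mutations
FR	73	192
CDR	41	81
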