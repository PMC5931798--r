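base_class	stratum	total_nucleotides	observed
GC	FR	927	56
GC	CDR	400	35
GC	ALL	1327	91
GC	OUTSIDE	4402	71
AT	FR	2531	54
AT	CDR	400	26
AT	ALL	2931	80
AT	OUTSIDE	3690	41
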