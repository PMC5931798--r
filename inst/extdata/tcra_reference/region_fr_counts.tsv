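region	total_nucleotides	syn	nsyn	total_mutations
FR1	3075	20	50	70
FR2	2091	12	27	39
FR3	5049	35	48	83
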