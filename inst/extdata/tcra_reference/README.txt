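Reference marginal counts from the published nurse shark TcR-alpha somatic
hypermutation survey (41 clones in 11 CDR3-identical clonal groups from two
animals). These are inputs: the package's statistics are recomputed from
them, exercising every formula without the original GenBank sequences.

mutability_counts.tsv  per-base consensus occurrences and observed mutation
                       counts over the whole V region (FR1..CDR3)
hotspot_counts.tsv     nucleotide and observed-mutation totals inside/outside
                       DGYW/WRCH (G:C) and WA/TW (A:T) hotspot motifs
region_fr_counts.tsv   framework-region SYN/NSYN mutation counts and
                       nucleotide denominators, summed over groups
tandem_counts.tsv      tandemly mutated bases and all mutations per region
                       class
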