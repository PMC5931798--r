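---
title: "Methods: consensus-based SHM analysis of antigen-receptor repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-based SHM analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmscope)
```

# The analysis model

## Clonal groups as the unit of observation

Without an assembled germline locus, somatic mutations cannot be called
against germline alleles. The analysis instead exploits V(D)J junctional
diversity: the CDR3-J nucleotide string (every base after the inferred
germline V end through the end of J) is effectively unique per founder
thymocyte, because exonuclease trimming and N/P addition are random. Clones
sharing a byte-identical CDR3-J within one individual are treated as one
clonal family; mutations are differences from the family's plurality
consensus. This is deliberately conservative, with two consequences the
package inherits rather than hides:

* **Junction censoring.** A clone whose CDR3-J itself mutated no longer
  matches its siblings' key and drops out as a singleton. Retained members
  are therefore identical in CDR3-J by construction, and measured CDR3
  frequencies are biased low. This matters for calibration (below).
* **Founder-shared mutations are invisible.** A mutation acquired before
  clonal expansion is in every member, hence in the consensus, hence never
  called. Consensus-based frequencies are a lower bound on the true
  per-cell mutation load.

Germline V/J boundaries are inferred from cross-individual agreement: a
base observed at the same alignment column in more than one animal is taken
as germline (two animals do not independently draw the same non-templated
base, barring short palindromic P overlaps). Scanning 5'→3', the germline V
extension ends at the first run of `break_threshold` consecutive columns
with no cross-individual shared base; the default threshold of 2 prevents a
lone allelic polymorphism from terminating the extension. All-gap columns
are uninformative and neither extend agreement nor count toward the break.
Simulations (1 clone per animal, default trimming) place both inferred
boundaries within ±2 nt of the trim-aware truth in well over 90% of
families; accuracy degrades when many clones per animal make coincidental
N-region matches likely.

## Mutation calling and effect classification

The consensus takes the plurality non-gap base per column; a column is a
gap only when gaps are the strict majority, so minority insertions never
enter the consensus. Base ties are broken by the first member in input
order (recorded in the `tie_columns` attribute); an IUPAC-ambiguity
alternative was rejected because downstream codon logic needs concrete
bases. Calls require both consensus and member base present: insertion
columns (consensus gap) are excluded from counts, and a member's gap
columns are subtracted from that member's denominators, so every frequency
is "changes per nucleotide actually sequenced".

Each substitution is classified by placing the observed base alone into its
consensus codon and comparing translations under the standard genetic code
— members of a tandem run are therefore assessed independently of their
neighbors. Stop-codon changes are nonsynonymous. The reading frame comes
from the region map's `frame_offset`, never from inference. Codons
containing a consensus gap are `UNDETERMINED`: counted in totals, excluded
from SYN/NSYN splits. Effects are only classified inside FR1..CDR3, where
the codon frame is stable on alignment columns; J and C substitutions are
tallied separately without an effect.

Tandem runs are maximal sets of ≥2 consecutive mutated alignment columns in
one member; a gap column always separates runs because it can carry no
call.

## Hotspot conventions

Motifs are scanned on the ungapped consensus only ("motifs created by the
mutation" never count), forward strand: DGYW/WRCH and WA/TW are mutual
reverse-complement pairs, so one-strand scanning covers both strands'
targets. Mutable offsets follow the SHM literature: the G of DGYW, the C of
WRCH, the A of WA, the T of TW. Overlapping windows are allowed; target
columns are deduplicated per base class. Note that a single 4-mer can match
both DGYW and WRCH (e.g. `AGCT`), contributing one G and one C target.

Enrichment compares observed mutation frequencies at target vs non-target
nucleotides of the same base class within FR+CDR, with expected counts
proportional to nucleotide shares, a df=1 goodness-of-fit χ², and a
one-tailed pooled-variance t-test on per-group frequencies.

## Statistics

* **Pooled frequencies are ratios of summed counts**, never means of
  per-group ratios (regression-tested against the wrong estimator).
* **Mutability index**: MI_b = O_b / (p_b · M). Occurrence-weighted mean MI
  is identically 1; expecteds sum to observeds (both asserted).
* **Paired χ² for substitution bias**: the statistic sums (O−E)²/E over the
  two bases of a pair — (G,C) or (A,T) — and is referred to df = 1. This
  df=1 paired construction is the one convention that reproduces the
  reference tables' printed p-values (0.0022, 0.0068) from their own counts
  and is documented here as a reverse-engineered convention.
* **t-tests** are unpaired, pooled-variance, one-tailed, with the clonal
  group as the observation unit: CDR > FR for region comparisons,
  periphery > thymus for tissue comparisons. Degenerate constant samples
  return p = 0.5 when means agree. No multiple-testing correction is
  applied by default, matching the field practice this analysis mirrors;
  `stats::p.adjust` can be applied to any returned column.

# The synthetic repertoire generator

`simulation_config()` defaults define study-like conditions and are frozen:
6 V genes at 90% identity, 4 J genes, V of 300 nt (25/8/17/7/40 codons for
FR1/CDR1/FR2/CDR2/FR3-core, IMGT-like), trims Uniform(0,6) per side, N/P
joins of 0–12 nt (with ≤2 palindromic nucleotides copied from untrimmed cut
ends), clonal families of 2–9 members across 2 individuals, per-nucleotide
rate 0.02, 4× G:C targeting at DGYW/WRCH, 2× A:T at WA/TW, 2× CDR
elevation, 2:1 transition bias, tandem seeding probability 0.25 with runs
of 2–4, and insertions of 3 or 18 nt at probability 0.01. Junctions are
resampled until in-frame and stop-free, as cloned productive receptors are.
With these defaults ~85–90% of simulated founder joins are unique, within
the "mostly unique, 0–34 nt" regime the analysis assumes; the length
ceiling is configurable and deliberately left at 12 nt, since nothing
downstream depends on the tail of the length distribution.

The alignment layout is fixed per family: V columns, a reserved 18-column
insertion slot at a codon boundary inside FR3 (all-gap unless a clone
carries an insertion, so region maps are constant across random draws), a
CDR3 block holding the last 9 V nt plus the left-aligned join pad, then J
(right-anchored, 5'-trim as leading gaps) and C. Keeping the insertion slot
codon-aligned preserves the downstream reading frame on alignment columns.

## Two-phase mutation process and renormalization

Position weights are per_base_rate × hotspot multiplier × CDR multiplier,
computed against the founder sequence (motifs are not re-scanned after each
mutation, mirroring the analysis's consensus-only convention). CDR3-J
columns are protected by default so the clonal-grouping truth is exact; a
flag opens them for sensitivity studies. Primary events are Bernoulli per
position; substituted bases are drawn with transition:transversion weights
κ:1:1; each event extends rightward into a tandem run of 2–4 bases with
probability 0.25.

Two design choices keep the generator's parameters *recoverable*:

1. **Marginal renormalization.** Primary probabilities are scaled so the
   expected mutated bases — including tandem extensions, whose expected
   count is computed exactly per seed column — average `per_base_rate` over
   mutable positions. Without this, multipliers would inflate the realized
   rate.
2. **Proportional extension thinning.** A run extension onto column *c* is
   accepted with probability w(c)/max(w). A weight-blind contiguous run
   smears hotspot-seeded mutations onto neighboring non-target columns and
   dilutes the realized in/out enrichment to ~2.5–2.9 for a 4× multiplier;
   with thinning, realized per-position rates stay proportional to the
   weights and the pipeline recovers the multiplier (median estimate
   ~3.4–4.0 at 50 groups × 5 members). The cost is a tandem-base share of
   ~15–20%, lower than the 38–50% seen in real shark data: per-position
   rate proportionality and a large weight-blind tandem share are
   mathematically incompatible, and the generator prioritizes the
   quantity the recovery analyses measure. Simulated tandem runs still
   span the realistic 2–4 bases.

Every founder consumes a derived RNG substream, so resizing one group
leaves all other draws unchanged, and the truth log (rearrangement events,
insertions, per-base mutation events with phase labels) replays every
emitted sequence byte-exactly.

## What the simulator does not emulate

Uniform base composition (real V genes are motif-enriched: ~57% of
mutations hit G:C in the reference data vs ~50% here), antigen- or
selection-driven clone dynamics, PCR/sequencing error, alignment error
(alignment is an input contract; the package never re-aligns), allelic
polymorphism beyond the two-individual germline rule, and D segments
(TcRα has none). Passing parameter-recovery tests therefore demonstrates
estimator correctness under the stated generative model, not robustness to
these real-data complications.

# Calibration design

The null calibration of the CDR-vs-FR test deserves a note. Under uniform
targeting, the identical-junction grouping still censors CDR3-J mutations
(retained members are identical there by construction), so the measured
CDR frequency is biased low and one-tailed p-values pile up near 1: the
pipeline's "null" is not null. The calibration therefore uses the
simulator's known lineages for grouping (`analyze_repertoire(lineages=)`)
with protection off and all multipliers at 1 — the data-generating process
is then genuinely null for the measured contrast, and the t-test's
p-values are uniform (KS test). This isolates the test machinery from the
grouping's documented conservatism rather than hiding that conservatism.

# Numerical and interface conventions

* Coordinates are 1-based inclusive alignment columns everywhere, including
  the region-config TSV (GFF-style); reports print 1-based columns.
* Region configs must tile FR1..CDR3 contiguously, with codon-multiple
  lengths outside the ragged CDR3, and carry the frame offset explicitly.
* Identity clustering for family assignment is single-linkage on pairwise
  ungapped identity with thresholds 0.85/0.90 (both configurable; 0.70/0.75
  appear in parts of the literature) — a mechanical approximation to
  tree-based assignment with manual cutting, documented as such.
* Unparseable tissue tokens map to OTHER with a warning, never an error;
  grouping treats OTHER as peripheral in tissue stratification.
* Degenerate inputs: empty FASTA → empty repertoire plus warning; no group
  of size ≥ 2 → warning and an empty-but-valid report bundle; zero
  outside-motif frequency → infinite enrichment ratio with warning; zero
  mutations → 0% tandem fraction, not NaN.

# Problem sizes

The test suite validates oracle equivalences on 1000 random 200-mers
(motifs), all 64 × 9 codon substitutions (effects), and 1000 random column
sets (tandems); parameter recovery runs 20 replicates of 50 groups × 5
members (rate, enrichment, transition fraction) and 200 null replicates of
12 groups × 4 members (calibration). These sizes give stable medians and
KS tests while keeping a full run in the low minutes; the workflow scripts
use the same conditions with fewer replicates for interactive use.
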