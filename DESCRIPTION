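Package: shmscope
Title: Somatic Hypermutation Analysis of T-Cell Receptor V Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies somatic hypermutation (SHM) in cloned antigen-receptor
    V-region cDNA repertoires. Reconstructs clonal families by exact CDR3-J
    nucleotide identity, derives per-family consensus sequences, calls and
    classifies point and tandem mutations (synonymous/nonsynonymous by
    independent single-base substitution), scans AID (DGYW/WRCH) and
    polymerase-eta (WA/TW) hotspot motifs, and produces region-stratified
    mutation frequencies, hotspot-enrichment tables, base mutability indices
    and substitution spectra. Includes a V(D)J rearrangement and two-phase SHM
    simulator with full ground-truth logs for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
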