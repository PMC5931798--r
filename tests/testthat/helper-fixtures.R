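# Small hand-built fixtures used across test files.

# A toy region map: FR1 1-6, CDR1 7-12, FR2 13-18, CDR2 19-24, FR3 25-30,
# CDR3 31-35 (ragged), J 36-38, C 39-41; frame starts at column 1.
toy_region_map <- function(family_id = "aV1") {
  tibble::tibble(
    family_id = family_id,
    region_label = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "J", "C"),
    start = as.integer(c(1, 7, 13, 19, 25, 31, 36, 39)),
    end = as.integer(c(6, 12, 18, 24, 30, 35, 38, 41)),
    frame_offset = 1L
  )
}

# Build an shm_repertoire directly from residue strings (all one family by
# default), bypassing file I/O.
toy_repertoire <- function(residues, seq_ids = NULL, family_id = "aV1",
                           individual_id = "S1", tissue = "THY",
                           regions = NULL) {
  n <- length(residues)
  if (is.null(seq_ids)) {
    seq_ids <- sprintf("%s_THY%02d_010116_%s", family_id, seq_len(n),
                       individual_id)
  }
  if (is.null(regions)) regions <- toy_region_map(family_id)
  seqs <- tibble::tibble(
    seq_id = seq_ids,
    family_id = rep_len(family_id, n),
    tissue = rep_len(tissue, n),
    individual_id = rep_len(individual_id, n),
    residues = residues
  )
  structure(list(sequences = seqs, regions = regions),
            class = "shm_repertoire")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent brute-force motif oracle: expand each IUPAC pattern to its
# explicit k-mer set and scan every window of the ungapped sequence.
oracle_scan_motifs <- function(consensus) {
  expand <- function(classes) {
    kmers <- do.call(expand.grid, c(rev(classes), stringsAsFactors = FALSE))
    apply(kmers[, rev(seq_along(classes)), drop = FALSE], 1, paste,
          collapse = "")
  }
  D <- c("A", "G", "T"); Y <- c("C", "T"); W <- c("A", "T")
  R <- c("A", "G"); H <- c("A", "C", "T")
  pats <- list(
    DGYW = list(kmers = expand(list(D, "G", Y, W)), offset = 1L),
    WRCH = list(kmers = expand(list(W, R, "C", H)), offset = 2L),
    WA   = list(kmers = expand(list(W, "A")), offset = 1L),
    TW   = list(kmers = expand(list("T", W)), offset = 0L)
  )
  ch_aln <- strsplit(consensus, "", fixed = TRUE)[[1]]
  keep <- which(ch_aln != "-")
  s <- paste(ch_aln[keep], collapse = "")
  gc <- integer(0); at <- integer(0)
  for (nm in names(pats)) {
    k <- nchar(pats[[nm]]$kmers[1])
    if (nchar(s) < k) next
    hits <- integer(0)
    for (i in 1:(nchar(s) - k + 1)) {
      if (substr(s, i, i + k - 1) %in% pats[[nm]]$kmers) hits <- c(hits, i)
    }
    targets <- keep[hits + pats[[nm]]$offset]
    if (nm %in% c("DGYW", "WRCH")) gc <- c(gc, targets) else at <- c(at, targets)
  }
  list(gc_targets = sort(unique(gc)), at_targets = sort(unique(at)))
}
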