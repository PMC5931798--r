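#' Scan a consensus for SHM hotspot motifs
#'
#' Finds AID deaminase targets — the G of `DGYW` and the C of `WRCH` — and
#' polymerase-eta targets — the A of `WA` and the T of `TW` — on the ungapped
#' consensus, mapping positions back to alignment columns. The two members of
#' each pair are mutual reverse complements, so scanning both patterns on the
#' coding strand covers AID targets on either strand. Overlapping windows are
#' all reported; target columns are deduplicated per class. Only motifs
#' present in the consensus count (motifs created by a mutation never do).
#'
#' IUPAC classes: D = A/G/T, Y = C/T, W = A/T, R = A/G, H = A/C/T.
#'
#' @param consensus Consensus string (may contain gaps).
#' @return List with `gc_targets` and `at_targets` (sorted integer alignment
#'   columns) and `windows`, a tibble of every motif window (motif,
#'   target_col, start_col — alignment coordinates of the mutable base and
#'   window start).
#' @export
scan_motifs <- function(consensus) {
  ch_aln <- strsplit(consensus, "", fixed = TRUE)[[1]]
  keep <- which(ch_aln != "-")
  ch <- ch_aln[keep]
  n <- length(ch)
  is_d <- ch %in% c("A", "G", "T")
  is_y <- ch %in% c("C", "T")
  is_w <- ch %in% c("A", "T")
  is_r <- ch %in% c("A", "G")
  is_h <- ch %in% c("A", "C", "T")

  win4 <- if (n >= 4) seq_len(n - 3) else integer(0)
  dgyw <- win4[is_d[win4] & ch[win4 + 1] == "G" & is_y[win4 + 2] & is_w[win4 + 3]]
  wrch <- win4[is_w[win4] & is_r[win4 + 1] & ch[win4 + 2] == "C" & is_h[win4 + 3]]
  win2 <- if (n >= 2) seq_len(n - 1) else integer(0)
  wa <- win2[is_w[win2] & ch[win2 + 1] == "A"]
  tw <- win2[ch[win2] == "T" & is_w[win2 + 1]]

  windows <- tibble::tibble(
    motif = c(rep("DGYW", length(dgyw)), rep("WRCH", length(wrch)),
              rep("WA", length(wa)), rep("TW", length(tw))),
    target_col = keep[c(dgyw + 1L, wrch + 2L, wa + 1L, tw)],
    start_col = keep[c(dgyw, wrch, wa, tw)]
  )
  gc_targets <- sort(unique(windows$target_col[windows$motif %in% c("DGYW", "WRCH")]))
  at_targets <- sort(unique(windows$target_col[windows$motif %in% c("WA", "TW")]))
  stopifnot(all(ch_aln[gc_targets] %in% c("G", "C")),
            all(ch_aln[at_targets] %in% c("A", "T")))
  list(gc_targets = gc_targets, at_targets = at_targets, windows = windows)
}

#' Flag mutation calls as inside/outside their class's hotspot motifs
#'
#' A call is in-hotspot iff its column belongs to the target set matching its
#' consensus base class (targets are class-pure by construction).
#'
#' @param calls Call tibble from [call_mutations()].
#' @param ann Hotspot annotation from [scan_motifs()].
#' @return The calls with `in_hotspot` (logical) and `motif`
#'   (DGYW_WRCH / WA_TW / NONE) columns added.
#' @export
annotate_hotspot_calls <- function(calls, ann) {
  in_gc <- calls$column %in% ann$gc_targets
  in_at <- calls$column %in% ann$at_targets
  stopifnot(all(calls$base_class[in_gc] == "GC"),
            all(calls$base_class[in_at] == "AT"))
  calls$in_hotspot <- in_gc | in_at
  motif <- rep("NONE", nrow(calls))
  motif[in_gc] <- "DGYW_WRCH"
  motif[in_at] <- "WA_TW"
  calls$motif <- motif
  calls
}

#' Count target and non-target nucleotides by class and stratum
#'
#' For each base class (GC: consensus G or C; AT: consensus A or T) and
#' stratum, counts nucleotides actually present in the member sequences
#' (consensus columns of that class, times members, minus member gaps),
#' within the framework (FR1+FR2+FR3) and CDR (CDR1+CDR2+CDR3) intervals.
#' Strata: `FR` and `CDR` are in-motif nucleotides inside those regions;
#' `ALL` is their sum; `OUTSIDE` is the class total minus in-motif. The
#' conservation `ALL + OUTSIDE = class total` holds by construction and is
#' asserted.
#'
#' @param ann Hotspot annotation from [scan_motifs()].
#' @param consensus Consensus string.
#' @param members Member tibble (for gap-aware denominators).
#' @param region_map The family's region map.
#' @return Tibble: base_class, stratum, total_nucleotides.
#' @export
count_targets_by_region <- function(ann, consensus, members, region_map) {
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mat <- residue_matrix(members$residues)
  depth <- colSums(mat != "-") # nucleotides present per column
  fr_cols <- region_columns(region_map, c("FR1", "FR2", "FR3"))
  cdr_cols <- region_columns(region_map, c("CDR1", "CDR2", "CDR3"))
  per_class <- function(class_bases, targets) {
    class_cols <- which(cons %in% class_bases)
    cls_fr <- intersect(class_cols, fr_cols)
    cls_cdr <- intersect(class_cols, cdr_cols)
    in_fr <- sum(depth[intersect(cls_fr, targets)])
    in_cdr <- sum(depth[intersect(cls_cdr, targets)])
    total <- sum(depth[c(cls_fr, cls_cdr)])
    c(FR = in_fr, CDR = in_cdr, ALL = in_fr + in_cdr,
      OUTSIDE = total - in_fr - in_cdr)
  }
  gc <- per_class(c("G", "C"), ann$gc_targets)
  at <- per_class(c("A", "T"), ann$at_targets)
  stopifnot(gc[["ALL"]] + gc[["OUTSIDE"]] == sum(gc[c("FR", "CDR")]) +
              gc[["OUTSIDE"]])
  tibble::tibble(
    base_class = rep(c("GC", "AT"), each = 4),
    stratum = rep(c("FR", "CDR", "ALL", "OUTSIDE"), 2),
    total_nucleotides = as.integer(c(gc, at))
  )
}

#' Hotspot enrichment from in/out counts
#'
#' Core arithmetic of the hotspot targeting analysis: observed mutation
#' frequencies inside and outside the motif target set, composition-expected
#' counts under uniform targeting, the in/out enrichment ratio, and a
#' goodness-of-fit chi-square (df = 1) of observed vs expected.
#'
#' @param observed_in,observed_out Observed mutation counts in/out of motifs.
#' @param nt_in,nt_out Nucleotide totals in/out of motifs.
#' @return List: freq_in_pct, freq_out_pct, expected_in, expected_out,
#'   enrichment_ratio, chisq_stat, chisq_p.
#' @export
hotspot_enrichment <- function(observed_in, nt_in, observed_out, nt_out) {
  total_obs <- observed_in + observed_out
  total_nt <- nt_in + nt_out
  expected_in <- total_obs * nt_in / total_nt
  expected_out <- total_obs * nt_out / total_nt
  freq_in <- 100 * observed_in / nt_in
  freq_out <- 100 * observed_out / nt_out
  if (freq_out == 0) {
    warning("outside-motif frequency is zero; enrichment ratio is infinite")
    ratio <- Inf
  } else {
    ratio <- freq_in / freq_out
  }
  stat <- (observed_in - expected_in)^2 / expected_in +
    (observed_out - expected_out)^2 / expected_out
  list(freq_in_pct = freq_in, freq_out_pct = freq_out,
       expected_in = expected_in, expected_out = expected_out,
       enrichment_ratio = ratio, chisq_stat = stat,
       chisq_p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Count motif windows per region
#'
#' Number of motif windows (not target nucleotides) whose mutable position
#' lies in each region; a window straddling a region boundary is assigned by
#' the region of its mutable base.
#'
#' @param consensus Consensus string.
#' @param region_map The family's region map.
#' @return Tibble: motif_class (DGYW_WRCH / WA_TW), region, n_windows.
#' @export
count_motifs_per_region <- function(consensus, region_map) {
  ann <- scan_motifs(consensus)
  w <- ann$windows
  w$motif_class <- ifelse(w$motif %in% c("DGYW", "WRCH"), "DGYW_WRCH", "WA_TW")
  w$region <- region_of_column(region_map, w$target_col)
  grid <- tidyr::expand_grid(motif_class = c("DGYW_WRCH", "WA_TW"),
                             region = region_map$region_label)
  counts <- dplyr::count(w[!is.na(w$region), ],
                         .data$motif_class, .data$region, name = "n_windows")
  out <- dplyr::left_join(grid, counts, by = c("motif_class", "region"))
  out$n_windows[is.na(out$n_windows)] <- 0L
  out
}
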