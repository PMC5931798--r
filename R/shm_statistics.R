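#' One-tailed pooled-variance Student t-test
#'
#' Unpaired, pooled variance, alternative `x > y`. Degenerate inputs are
#' handled explicitly: identical constant samples give p = 0.5 (no evidence
#' of direction), constant samples with differing means give p near 0 or 1
#' by direction.
#'
#' @param x,y Numeric samples (observation unit: clonal group).
#' @return One-tailed p-value, or NA (with a warning) when either sample has
#'   fewer than 2 observations.
#' @keywords internal
t_test_one_tailed <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    warning("t-test skipped: fewer than 2 observations in a sample")
    return(NA_real_)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(0.5)
    return(if (mean(x) > mean(y)) 0 else 1)
  }
  stats::t.test(x, y, alternative = "greater", var.equal = TRUE)$p.value
}

#' Base mutability indices from occurrence and observed counts
#'
#' For each nucleotide, the expected mutation count is its compositional
#' probability (occurrence / total occurrence) times the total observed
#' mutations; the mutability index (MI) is observed / expected, with 1.00
#' indicating mutation proportional to composition. Substitution bias is
#' tested pairwise for (G, C) and (A, T): the chi-square statistic sums
#' (O - E)^2 / E over the two bases of a pair and is referred to df = 1.
#'
#' @param occurrence Named vector (names among A, C, G, T) of nucleotide
#'   occurrences in the consensus sequences (times members present).
#' @param observed Named vector of observed mutation counts per consensus
#'   base.
#' @return Tibble with rows G, C, A, T and a totals row: occurrence,
#'   probability, observed, expected, mutability_index, pair_chisq_p (on the
#'   leading row of each pair). The pair tests are also attached as attribute
#'   `"chisq"`.
#' @export
mutability_table <- function(occurrence, observed) {
  bases <- c("G", "C", "A", "T")
  stopifnot(all(bases %in% names(occurrence)), all(bases %in% names(observed)))
  occ <- as.numeric(occurrence[bases])
  obs <- as.numeric(observed[bases])
  total_occ <- sum(occ)
  total_obs <- sum(obs)
  prob <- occ / total_occ
  expected <- prob * total_obs
  mi <- ifelse(expected > 0, obs / expected, NA_real_)
  pair_chisq <- function(idx) {
    if (any(expected[idx] == 0)) return(c(NA_real_, NA_real_))
    stat <- sum((obs[idx] - expected[idx])^2 / expected[idx])
    c(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  gc <- pair_chisq(1:2)
  at <- pair_chisq(3:4)
  chisq <- tibble::tibble(pair = c("GC", "AT"),
                          statistic = c(gc[1], at[1]),
                          p = c(gc[2], at[2]))
  tab <- tibble::tibble(
    base = c(bases, "Total"),
    occurrence = c(occ, total_occ),
    probability = c(prob, 1),
    observed = c(obs, total_obs),
    expected = c(expected, sum(expected)),
    mutability_index = c(mi, NA_real_),
    pair_chisq_p = c(gc[2], NA, at[2], NA, NA)
  )
  attr(tab, "chisq") <- chisq
  tab
}

#' Pooled mutation frequency
#'
#' The pooled frequency over groups or regions is the ratio of total counts,
#' never the mean of per-group ratios.
#'
#' @param mutations,nucleotides Numeric vectors of per-stratum counts.
#' @return `sum(mutations) / sum(nucleotides)` (substitutions per nucleotide).
#' @export
pooled_frequency <- function(mutations, nucleotides) {
  sum(mutations) / sum(nucleotides)
}

#' Fraction of mutations occurring in tandem
#'
#' @param tandem_bases Count(s) of tandemly mutated bases.
#' @param all_mutations Count(s) of all mutations (tandem + point).
#' @return Percentage of mutations that are tandem (0 when there are no
#'   mutations, never NaN).
#' @export
tandem_fraction <- function(tandem_bases, all_mutations) {
  tot <- sum(all_mutations)
  if (tot == 0) return(0)
  100 * sum(tandem_bases) / tot
}

#' @keywords internal
region_class_of <- function(region) {
  dplyr::case_when(
    region %in% c("FR1", "FR2", "FR3") ~ "FR",
    region %in% c("CDR1", "CDR2", "CDR3") ~ "CDR",
    TRUE ~ region
  )
}

#' Per-group, per-region mutation frequencies
#'
#' One row per analyzed group and region with the gap-aware nucleotide
#' denominator, SYN/NSYN/undetermined counts and the percentage frequency,
#' followed by pooled rows (`group_id = "POOLED"`) whose frequencies are
#' total-count ratios across groups.
#'
#' @param analysis An `shm_analysis` from [analyze_repertoire()].
#' @return Tibble: group_id, region, n_sequences, total_nucleotides, syn,
#'   nsyn, undetermined, total_mutations, freq_pct.
#' @export
region_frequency_table <- function(analysis) {
  per_group <- analysis$region_totals
  calls <- analysis$calls
  tally <- dplyr::summarise(
    dplyr::group_by(calls, .data$group_id, .data$region),
    syn = sum(.data$effect %in% "SYN"),
    nsyn = sum(.data$effect %in% "NSYN"),
    undetermined = sum(.data$effect %in% "UNDETERMINED" | is.na(.data$effect)),
    total_mutations = dplyr::n(),
    .groups = "drop")
  out <- dplyr::left_join(per_group, tally, by = c("group_id", "region"))
  for (col in c("syn", "nsyn", "undetermined", "total_mutations")) {
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out$freq_pct <- ifelse(out$total_nucleotides > 0,
                         100 * out$total_mutations / out$total_nucleotides, 0)
  pooled <- dplyr::summarise(
    dplyr::group_by(out, .data$region),
    group_id = "POOLED",
    n_sequences = sum(.data$n_sequences),
    total_nucleotides = sum(.data$total_nucleotides),
    syn = sum(.data$syn), nsyn = sum(.data$nsyn),
    undetermined = sum(.data$undetermined),
    total_mutations = sum(.data$total_mutations),
    .groups = "drop")
  pooled$freq_pct <- ifelse(pooled$total_nucleotides > 0,
                            100 * pooled$total_mutations / pooled$total_nucleotides, 0)
  dplyr::bind_rows(out, pooled[, names(out)])
}

#' Pooled FR/CDR (and J/C) summary
#'
#' Region-class totals across all groups, with frequencies as substitutions
#' per nucleotide (the "S/N" convention) and as percentages.
#'
#' @param analysis An `shm_analysis`.
#' @return Tibble: region_class, total_nucleotides, syn, nsyn, undetermined,
#'   total_mutations, freq (S/N), freq_pct, syn_freq, nsyn_freq.
#' @export
region_class_summary <- function(analysis) {
  tab <- region_frequency_table(analysis)
  tab <- tab[tab$group_id != "POOLED", ]
  tab$region_class <- region_class_of(tab$region)
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$region_class),
    total_nucleotides = sum(.data$total_nucleotides),
    syn = sum(.data$syn), nsyn = sum(.data$nsyn),
    undetermined = sum(.data$undetermined),
    total_mutations = sum(.data$total_mutations),
    .groups = "drop")
  out$freq <- ifelse(out$total_nucleotides > 0,
                     out$total_mutations / out$total_nucleotides, 0)
  out$freq_pct <- 100 * out$freq
  out$syn_freq <- ifelse(out$total_nucleotides > 0,
                         out$syn / out$total_nucleotides, 0)
  out$nsyn_freq <- ifelse(out$total_nucleotides > 0,
                          out$nsyn / out$total_nucleotides, 0)
  out[order(match(out$region_class, c("FR", "CDR", "J", "C"))), ]
}

#' Tandem mutation table
#'
#' Per group and region class (FR, CDR): counts of tandem runs by length
#' (2, 3, 4+), the number of tandemly mutated bases, all mutations, and the
#' percentage of mutations occurring in tandem; plus a totals row per class.
#' A run straddling an FR/CDR boundary contributes its bases to each class's
#' tandem-base count and is binned by its within-class length.
#'
#' @param analysis An `shm_analysis`.
#' @return Tibble: group_id, region_class, runs_len2, runs_len3, runs_len4p,
#'   tandem_bases, all_mutations, tandem_freq_pct.
#' @export
tandem_table <- function(analysis) {
  calls <- analysis$calls
  calls$region_class <- region_class_of(calls$region)
  calls <- calls[calls$region_class %in% c("FR", "CDR"), ]
  grid <- tidyr::expand_grid(group_id = analysis$groups$group_id,
                             region_class = c("FR", "CDR"))
  if (nrow(calls) == 0) {
    stats_tbl <- grid
    stats_tbl$runs_len2 <- stats_tbl$runs_len3 <- stats_tbl$runs_len4p <- 0L
    stats_tbl$tandem_bases <- stats_tbl$all_mutations <- 0L
  } else {
    tandem <- calls[!is.na(calls$tandem_run_id), ]
    run_lens <- dplyr::summarise(
      dplyr::group_by(tandem, .data$group_id, .data$region_class,
                      .data$seq_id, .data$tandem_run_id),
      len = dplyr::n(), .groups = "drop")
    runs <- dplyr::summarise(
      dplyr::group_by(run_lens, .data$group_id, .data$region_class),
      runs_len2 = sum(.data$len == 2),
      runs_len3 = sum(.data$len == 3),
      runs_len4p = sum(.data$len >= 4),
      .groups = "drop")
    bases <- dplyr::summarise(
      dplyr::group_by(calls, .data$group_id, .data$region_class),
      tandem_bases = sum(!is.na(.data$tandem_run_id)),
      all_mutations = dplyr::n(), .groups = "drop")
    stats_tbl <- dplyr::left_join(grid, runs, by = c("group_id", "region_class"))
    stats_tbl <- dplyr::left_join(stats_tbl, bases, by = c("group_id", "region_class"))
    for (col in c("runs_len2", "runs_len3", "runs_len4p", "tandem_bases",
                  "all_mutations")) {
      stats_tbl[[col]][is.na(stats_tbl[[col]])] <- 0L
    }
  }
  totals <- dplyr::summarise(
    dplyr::group_by(stats_tbl, .data$region_class),
    group_id = "TOTAL",
    dplyr::across(c("runs_len2", "runs_len3", "runs_len4p",
                    "tandem_bases", "all_mutations"), sum),
    .groups = "drop")
  out <- dplyr::bind_rows(stats_tbl, totals[, names(stats_tbl)])
  out$tandem_freq_pct <- mapply(tandem_fraction, out$tandem_bases,
                                out$all_mutations)
  out
}

#' Mutability indices from an analysis
#'
#' Occurrences are consensus-base counts over the chosen stratum's columns,
#' weighted by the number of members actually carrying a base there;
#' observed counts are mutation calls by consensus base.
#'
#' @param analysis An `shm_analysis`.
#' @param stratum `"ALL"` (FR1..CDR3), `"FR"` or `"CDR"`.
#' @return A [mutability_table()].
#' @export
mutability_from_analysis <- function(analysis, stratum = c("ALL", "FR", "CDR")) {
  stratum <- match.arg(stratum)
  labels <- switch(stratum,
                   ALL = V_REGION_LABELS,
                   FR = c("FR1", "FR2", "FR3"),
                   CDR = c("CDR1", "CDR2", "CDR3"))
  occ <- c(A = 0, C = 0, G = 0, T = 0)
  for (gid in analysis$groups$group_id) {
    cons <- strsplit(analysis$consensus[[gid]], "", fixed = TRUE)[[1]]
    members <- group_members(analysis$repertoire,
                             analysis$groups[analysis$groups$group_id == gid, ])
    rm <- family_region_map(analysis$repertoire$regions,
                            analysis$groups$family_id[analysis$groups$group_id == gid])
    cols <- region_columns(rm, labels)
    depth <- colSums(residue_matrix(members$residues) != "-")
    for (b in names(occ)) {
      occ[b] <- occ[b] + sum(depth[cols][cons[cols] == b])
    }
  }
  calls <- analysis$calls
  calls <- calls[region_class_of(calls$region) %in%
                   (if (stratum == "ALL") c("FR", "CDR") else stratum), ]
  obs <- c(A = sum(calls$consensus_base == "A"),
           C = sum(calls$consensus_base == "C"),
           G = sum(calls$consensus_base == "G"),
           T = sum(calls$consensus_base == "T"))
  mutability_table(occ, obs)
}

#' Substitution spectrum
#'
#' Transition (A<->G, C<->T) fraction, the C:A / G:T transversion category,
#' and the share of mutations hitting G:C consensus bases.
#'
#' @param calls Call tibble with `consensus_base` and `observed_base`.
#' @return List: n, gc_mutation_pct, transition_pct, ca_gt_transversion_pct,
#'   other_transversion_pct.
#' @export
substitution_spectrum <- function(calls) {
  n <- nrow(calls)
  if (n == 0) {
    return(list(n = 0L, gc_mutation_pct = NA_real_, transition_pct = NA_real_,
                ca_gt_transversion_pct = NA_real_,
                other_transversion_pct = NA_real_))
  }
  pair <- paste0(calls$consensus_base, calls$observed_base)
  is_transition <- pair %in% c("AG", "GA", "CT", "TC")
  is_ca_gt <- pair %in% c("CA", "AC", "GT", "TG")
  list(n = n,
       gc_mutation_pct = 100 * mean(calls$consensus_base %in% c("G", "C")),
       transition_pct = 100 * mean(is_transition),
       ca_gt_transversion_pct = 100 * mean(is_ca_gt),
       other_transversion_pct = 100 * mean(!is_transition & !is_ca_gt))
}

#' Hotspot enrichment table across groups
#'
#' Mirrors the hotspot targeting analysis: per base class, observed and
#' expected mutations inside motif targets (within FR, within CDR, and
#' overall) and outside them, percentage frequencies, the in/out enrichment
#' ratio, a df = 1 goodness-of-fit chi-square, and a one-tailed
#' pooled-variance t-test of per-group in-motif vs outside frequencies.
#'
#' @param analysis An `shm_analysis`.
#' @return Tibble: base_class, stratum, total_nucleotides, observed,
#'   expected, freq_pct, enrichment_ratio, chisq_p, ttest_p (ratio and tests
#'   on the ALL row of each class).
#' @export
hotspot_enrichment_table <- function(analysis) {
  counts <- analysis$target_counts # per group
  calls <- analysis$calls
  calls$region_class <- region_class_of(calls$region)
  calls <- calls[calls$region_class %in% c("FR", "CDR"), ]
  obs_tbl <- function(df) {
    tibble::tibble(
      stratum = c("FR", "CDR", "ALL", "OUTSIDE"),
      observed = c(sum(df$in_hotspot & df$region_class == "FR"),
                   sum(df$in_hotspot & df$region_class == "CDR"),
                   sum(df$in_hotspot),
                   sum(!df$in_hotspot)))
  }
  out <- vector("list", 2)
  for (k in seq_along(c("GC", "AT"))) {
    cls <- c("GC", "AT")[k]
    cls_counts <- dplyr::summarise(
      dplyr::group_by(counts[counts$base_class == cls, ], .data$stratum),
      total_nucleotides = sum(.data$total_nucleotides), .groups = "drop")
    cls_calls <- calls[calls$base_class == cls, ]
    obs <- obs_tbl(cls_calls)
    tab <- dplyr::left_join(cls_counts, obs, by = "stratum")
    nt <- stats::setNames(tab$total_nucleotides, tab$stratum)
    ob <- stats::setNames(tab$observed, tab$stratum)
    enr <- hotspot_enrichment(ob[["ALL"]], nt[["ALL"]],
                              ob[["OUTSIDE"]], nt[["OUTSIDE"]])
    class_total_nt <- nt[["ALL"]] + nt[["OUTSIDE"]]
    class_total_obs <- ob[["ALL"]] + ob[["OUTSIDE"]]
    tab$expected <- class_total_obs * tab$total_nucleotides / class_total_nt
    tab$freq_pct <- ifelse(tab$total_nucleotides > 0,
                           100 * tab$observed / tab$total_nucleotides, 0)
    tab$base_class <- cls
    tab$enrichment_ratio <- ifelse(tab$stratum == "ALL",
                                   enr$enrichment_ratio, NA_real_)
    tab$chisq_p <- ifelse(tab$stratum == "ALL", enr$chisq_p, NA_real_)
    # group-level in vs out frequencies, one-tailed (in > out)
    per_grp <- dplyr::group_by(counts[counts$base_class == cls &
                                        counts$stratum %in% c("ALL", "OUTSIDE"), ],
                               .data$group_id, .data$stratum)
    per_grp <- dplyr::summarise(per_grp,
                                nt = sum(.data$total_nucleotides),
                                .groups = "drop")
    grp_obs <- dplyr::summarise(
      dplyr::group_by(cls_calls, .data$group_id,
                      stratum = ifelse(.data$in_hotspot, "ALL", "OUTSIDE")),
      observed = dplyr::n(), .groups = "drop")
    per_grp <- dplyr::left_join(per_grp, grp_obs, by = c("group_id", "stratum"))
    per_grp$observed[is.na(per_grp$observed)] <- 0L
    per_grp$freq <- ifelse(per_grp$nt > 0, per_grp$observed / per_grp$nt, 0)
    wide <- tidyr::pivot_wider(per_grp[, c("group_id", "stratum", "freq")],
                               names_from = "stratum", values_from = "freq")
    ttest_p <- t_test_one_tailed(wide$ALL, wide$OUTSIDE)
    tab$ttest_p <- ifelse(tab$stratum == "ALL", ttest_p, NA_real_)
    tab$stratum <- factor(tab$stratum, levels = c("FR", "CDR", "ALL", "OUTSIDE"))
    tab <- tab[order(tab$stratum), ]
    tab$stratum <- as.character(tab$stratum)
    out[[k]] <- tab[, c("base_class", "stratum", "total_nucleotides",
                        "observed", "expected", "freq_pct",
                        "enrichment_ratio", "chisq_p", "ttest_p")]
  }
  dplyr::bind_rows(out)
}

#' Tissue-stratified mutation frequencies
#'
#' Splits member sequences into thymus (THY) and periphery (PBL, SPV,
#' SPLEEN, OTHER) and reports per-region N/S/ALL counts, nucleotide totals
#' and percentage frequencies, plus one-tailed t-tests (periphery > thymus,
#' unit = group) on FR and CDR frequencies. With fewer than 2 groups in a
#' tissue class the tests are skipped with a warning.
#'
#' @param analysis An `shm_analysis`.
#' @return List with `table` (tissue_class, region, nsyn, syn, total,
#'   total_nucleotides, freq_pct) and `tests` (region_class, p).
#' @export
tissue_stratified_table <- function(analysis) {
  rep <- analysis$repertoire
  seq_tissue <- stats::setNames(
    ifelse(rep$sequences$tissue == "THY", "thymus", "periphery"),
    rep$sequences$seq_id)
  calls <- analysis$calls
  calls$tissue_class <- seq_tissue[calls$seq_id]
  # gap-aware denominators per member, split by tissue
  denoms <- list()
  for (i in seq_len(nrow(analysis$groups))) {
    grp <- analysis$groups[i, ]
    members <- group_members(rep, grp)
    rm <- family_region_map(rep$regions, grp$family_id)
    for (j in seq_len(nrow(members))) {
      tot <- region_nucleotide_totals(members[j, ], rm)
      tot$tissue_class <- seq_tissue[[members$seq_id[j]]]
      tot$group_id <- grp$group_id
      denoms[[length(denoms) + 1]] <- tot
    }
  }
  denoms <- dplyr::bind_rows(denoms)
  nt <- dplyr::summarise(
    dplyr::group_by(denoms, .data$tissue_class, .data$region),
    total_nucleotides = sum(.data$total_nucleotides), .groups = "drop")
  mut <- dplyr::summarise(
    dplyr::group_by(calls, .data$tissue_class, .data$region),
    nsyn = sum(.data$effect %in% "NSYN"),
    syn = sum(.data$effect %in% "SYN"),
    total = dplyr::n(), .groups = "drop")
  tab <- dplyr::left_join(nt, mut, by = c("tissue_class", "region"))
  for (col in c("nsyn", "syn", "total")) tab[[col]][is.na(tab[[col]])] <- 0L
  tab$freq_pct <- ifelse(tab$total_nucleotides > 0,
                         100 * tab$total / tab$total_nucleotides, 0)
  # group-level FR/CDR frequencies per tissue class for the tests
  denoms$region_class <- region_class_of(denoms$region)
  calls$region_class <- region_class_of(calls$region)
  grp_nt <- dplyr::summarise(
    dplyr::group_by(denoms[denoms$region_class %in% c("FR", "CDR"), ],
                    .data$group_id, .data$tissue_class, .data$region_class),
    nt = sum(.data$total_nucleotides), .groups = "drop")
  grp_mut <- dplyr::summarise(
    dplyr::group_by(calls[calls$region_class %in% c("FR", "CDR"), ],
                    .data$group_id, .data$tissue_class, .data$region_class),
    m = dplyr::n(), .groups = "drop")
  grp <- dplyr::left_join(grp_nt, grp_mut,
                          by = c("group_id", "tissue_class", "region_class"))
  grp$m[is.na(grp$m)] <- 0L
  grp$freq <- ifelse(grp$nt > 0, grp$m / grp$nt, 0)
  tests <- tibble::tibble(region_class = c("FR", "CDR"), p = NA_real_)
  for (rc in tests$region_class) {
    thy <- grp$freq[grp$tissue_class == "thymus" & grp$region_class == rc]
    per <- grp$freq[grp$tissue_class == "periphery" & grp$region_class == rc]
    if (length(thy) < 2 || length(per) < 2) {
      warning("tissue comparison (", rc,
              ") skipped: a tissue class has < 2 groups")
    } else {
      tests$p[tests$region_class == rc] <- t_test_one_tailed(per, thy)
    }
  }
  list(table = tab, tests = tests)
}

#' Compare CDR and FR mutation frequencies across groups
#'
#' One-tailed (CDR > FR) pooled-variance t-tests on per-group frequencies
#' for all mutations, NSYN only and SYN only.
#'
#' @param analysis An `shm_analysis`.
#' @return Tibble: mutation_class (ALL/NSYN/SYN), mean_cdr_freq,
#'   mean_fr_freq, p.
#' @export
compare_cdr_fr <- function(analysis) {
  if (nrow(analysis$groups) < 2) {
    stop("compare_cdr_fr needs >= 2 clonal groups")
  }
  tab <- region_frequency_table(analysis)
  tab <- tab[tab$group_id != "POOLED", ]
  tab$region_class <- region_class_of(tab$region)
  tab <- tab[tab$region_class %in% c("FR", "CDR"), ]
  grp <- dplyr::summarise(
    dplyr::group_by(tab, .data$group_id, .data$region_class),
    nt = sum(.data$total_nucleotides),
    all = sum(.data$total_mutations),
    nsyn = sum(.data$nsyn), syn = sum(.data$syn), .groups = "drop")
  out <- vector("list", 3)
  classes <- c(ALL = "all", NSYN = "nsyn", SYN = "syn")
  for (k in seq_along(classes)) {
    grp$freq <- ifelse(grp$nt > 0, grp[[classes[k]]] / grp$nt, 0)
    cdr <- grp$freq[grp$region_class == "CDR"]
    fr <- grp$freq[grp$region_class == "FR"]
    out[[k]] <- tibble::tibble(mutation_class = names(classes)[k],
                               mean_cdr_freq = mean(cdr),
                               mean_fr_freq = mean(fr),
                               p = t_test_one_tailed(cdr, fr))
  }
  dplyr::bind_rows(out)
}

#' Average motif windows per region across groups
#'
#' @param analysis An `shm_analysis`.
#' @return Tibble: motif_class, region, mean_windows (averaged over groups).
#' @export
motif_region_summary <- function(analysis) {
  per_group <- vector("list", nrow(analysis$groups))
  for (i in seq_len(nrow(analysis$groups))) {
    grp <- analysis$groups[i, ]
    rm <- family_region_map(analysis$repertoire$regions, grp$family_id)
    tab <- count_motifs_per_region(analysis$consensus[[grp$group_id]], rm)
    tab$group_id <- grp$group_id
    per_group[[i]] <- tab
  }
  tab <- dplyr::bind_rows(per_group)
  dplyr::summarise(dplyr::group_by(tab, .data$motif_class, .data$region),
                   mean_windows = mean(.data$n_windows), .groups = "drop")
}
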