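ref_dir <- system.file("extdata", "tcra_reference", package = "shmscope")
if (ref_dir == "") ref_dir <- file.path("..", "..", "inst", "extdata",
                                        "tcra_reference")

test_that("mutability indices and paired chi-squares follow their definitions", {
  counts <- readr::read_tsv(file.path(ref_dir, "mutability_counts.tsv"),
                            show_col_types = FALSE)
  occ <- stats::setNames(counts$occurrence, counts$base)
  obs <- stats::setNames(counts$observed, counts$base)
  tab <- mutability_table(occ, obs)
  g <- tab[tab$base == "G", ]
  c_ <- tab[tab$base == "C", ]
  expect_equal(g$expected, 65.05, tolerance = 0.0001)
  expect_equal(round(g$mutability_index, 2), 1.18)
  expect_equal(c_$expected, 63.68, tolerance = 0.0001)
  expect_equal(round(c_$mutability_index, 2), 1.33)
  chisq <- attr(tab, "chisq")
  expect_equal(chisq$statistic[chisq$pair == "GC"], 9.33, tolerance = 0.001)
  expect_equal(chisq$p[chisq$pair == "GC"], 0.0022, tolerance = 0.01)
  expect_equal(chisq$p[chisq$pair == "AT"], 0.0068, tolerance = 0.01)
  # observed == expected -> MI 1 everywhere
  flat <- mutability_table(c(G = 100, C = 200, A = 300, T = 400),
                           c(G = 10, C = 20, A = 30, T = 40))
  expect_true(all(flat$mutability_index[flat$base != "Total"] == 1))
})

test_that("occurrence-weighted mean mutability index is exactly 1", {
  set.seed(11)
  for (i in 1:50) {
    occ <- stats::setNames(sample(50:5000, 4), c("A", "C", "G", "T"))
    obs <- stats::setNames(sample(0:100, 4), c("A", "C", "G", "T"))
    if (sum(obs) == 0) next
    tab <- mutability_table(occ, obs)
    rows <- tab$base != "Total"
    expect_equal(sum(tab$probability[rows] * tab$mutability_index[rows]), 1)
    # expectation conservation
    expect_equal(sum(tab$expected[rows]), sum(tab$observed[rows]))
  }
})

test_that("pooled frequency is the ratio of totals, not the mean of ratios", {
  m <- c(1, 10); n <- c(10, 1000)
  expect_equal(pooled_frequency(m, n), 11 / 1010)
  wrong <- mean(m / n) # the deliberately wrong estimator
  expect_false(isTRUE(all.equal(pooled_frequency(m, n), wrong)))
  # and the analysis table's POOLED rows obey the same rule
  cfg <- simulation_config(seed = 71, n_founders = 8)
  sim <- generate_repertoire(cfg)
  a <- analyze_repertoire(sim$repertoire)
  tab <- region_frequency_table(a)
  per <- tab[tab$group_id != "POOLED", ]
  pooled <- tab[tab$group_id == "POOLED", ]
  for (r in pooled$region) {
    expect_equal(pooled$freq_pct[pooled$region == r],
                 100 * sum(per$total_mutations[per$region == r]) /
                   sum(per$total_nucleotides[per$region == r]))
  }
})

test_that("a hand-built group yields the expected per-region frequency", {
  rm <- toy_region_map() # CDR1 = cols 7-12
  base <- paste(rep("A", 41), collapse = "")
  mutant <- paste0(substr(base, 1, 6), "G", substr(base, 8, 41))
  rep <- toy_repertoire(c(base, base, mutant),
                        seq_ids = sprintf("aV1_THY%02d_010116_S1", 1:3))
  a <- analyze_repertoire(rep)
  tab <- region_frequency_table(a)
  cdr1 <- tab[tab$region == "CDR1" & tab$group_id != "POOLED", ]
  expect_equal(cdr1$total_mutations, 1L)
  expect_equal(cdr1$total_nucleotides, 18L) # 6 columns x 3 members
  expect_equal(cdr1$freq_pct, 100 / 18)
  # zero-mutation regions still emit rows
  expect_true(all(c("FR1", "J", "C") %in% tab$region))
})

test_that("tandem tables count runs by length and never divide by zero", {
  expect_equal(tandem_fraction(3, 4), 75)
  expect_equal(tandem_fraction(0, 0), 0)
  expect_equal(tandem_fraction(c(73), c(192)), 38.0, tolerance = 0.001)
  cfg <- simulation_config(seed = 72, n_founders = 10)
  sim <- generate_repertoire(cfg)
  a <- analyze_repertoire(sim$repertoire)
  tt <- tandem_table(a)
  tot <- tt[tt$group_id == "TOTAL", ]
  per <- tt[tt$group_id != "TOTAL", ]
  for (rc in c("FR", "CDR")) {
    expect_equal(tot$tandem_bases[tot$region_class == rc],
                 sum(per$tandem_bases[per$region_class == rc]))
    expect_equal(tot$all_mutations[tot$region_class == rc],
                 sum(per$all_mutations[per$region_class == rc]))
  }
  # run-length bins against the call-level truth
  calls <- a$calls[a$calls$region %in% c("FR1", "FR2", "FR3",
                                         "CDR1", "CDR2", "CDR3"), ]
  tand <- calls[!is.na(calls$tandem_run_id), ]
  expect_equal(sum(tot$tandem_bases), nrow(tand))
})

test_that("the substitution spectrum splits transitions and transversions", {
  calls <- tibble::tibble(consensus_base = c("G", "C", "A"),
                          observed_base = c("A", "T", "C"))
  sp <- substitution_spectrum(calls)
  expect_equal(sp$transition_pct, 100 * 2 / 3)
  expect_equal(sp$ca_gt_transversion_pct, 100 / 3)
  expect_equal(sp$gc_mutation_pct, 100 * 2 / 3)
  single <- substitution_spectrum(tibble::tibble(consensus_base = "G",
                                                 observed_base = "T"))
  expect_equal(single$ca_gt_transversion_pct, 100)
  empty <- substitution_spectrum(tibble::tibble(consensus_base = character(),
                                                observed_base = character()))
  expect_equal(empty$n, 0L)
})

test_that("CDR-vs-FR comparison is one-tailed with group-level units", {
  # strong CDR elevation: small p in the expected direction
  cfg <- simulation_config(seed = 73, n_founders = 15, cdr_multiplier = 8,
                           gc_hotspot_multiplier = 1,
                           at_hotspot_multiplier = 1)
  sim <- generate_repertoire(cfg)
  a <- analyze_repertoire(sim$repertoire)
  res <- compare_cdr_fr(a)
  expect_identical(res$mutation_class, c("ALL", "NSYN", "SYN"))
  expect_lt(res$p[res$mutation_class == "ALL"], 0.05)
  expect_gt(res$mean_cdr_freq[1], res$mean_fr_freq[1])
  # fewer than 2 groups is an error
  one <- analyze_repertoire(toy_repertoire(rep(paste(rep("A", 41),
                                                     collapse = ""), 2)))
  expect_error(compare_cdr_fr(one), ">= 2")
})

test_that("tissue stratification pools THY against the periphery", {
  cfg <- simulation_config(seed = 74, n_founders = 12)
  sim <- generate_repertoire(cfg)
  a <- analyze_repertoire(sim$repertoire)
  res <- tissue_stratified_table(a)
  expect_setequal(unique(res$table$tissue_class), c("thymus", "periphery"))
  # tissue-split denominators add back to the group totals
  joint <- dplyr::summarise(
    dplyr::group_by(res$table, .data$region),
    nt = sum(.data$total_nucleotides), .groups = "drop")
  full <- dplyr::summarise(
    dplyr::group_by(a$region_totals, .data$region),
    nt = sum(.data$total_nucleotides), .groups = "drop")
  both <- dplyr::left_join(joint, full, by = "region")
  expect_equal(both$nt.x, both$nt.y)
  expect_true(all(res$tests$region_class %in% c("FR", "CDR")))
  # single-tissue data: tests are skipped with a warning
  rep2 <- sim$repertoire
  rep2$sequences$tissue <- "THY"
  a2 <- analyze_repertoire(rep2)
  warns <- testthat::capture_warnings(res2 <- tissue_stratified_table(a2))
  expect_true(all(grepl("skipped", warns)))
  expect_length(warns, 2)
  expect_true(all(is.na(res2$tests$p)))
})

test_that("motif windows per region average across groups", {
  cfg <- simulation_config(seed = 75, n_founders = 8)
  sim <- generate_repertoire(cfg)
  a <- analyze_repertoire(sim$repertoire)
  ms <- motif_region_summary(a)
  expect_setequal(unique(ms$motif_class), c("DGYW_WRCH", "WA_TW"))
  expect_true(all(ms$mean_windows >= 0))
  # FR3 is the longest region: it should carry the most G/C motif windows
  dg <- ms[ms$motif_class == "DGYW_WRCH", ]
  expect_equal(dg$region[which.max(dg$mean_windows)], "FR3")
})
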