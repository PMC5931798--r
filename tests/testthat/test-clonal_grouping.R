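# 41-column toy alignment: CDR3 = cols 31-35, J = 36-38 (see helper).
pad_seq <- function(cdr3j, prefix = NULL) {
  if (is.null(prefix)) prefix <- paste(rep("A", 30), collapse = "")
  stopifnot(nchar(cdr3j) == 8)
  paste0(prefix, cdr3j, "GGC")
}

test_that("CDR3-J keys strip gaps and ignore V-segment differences", {
  rm <- toy_region_map()
  s1 <- pad_seq("TG-CAGGT")
  expect_identical(extract_cdr3j_key(s1, rm), "TGCAGGT")
  all_gap <- pad_seq("--------")
  expect_identical(extract_cdr3j_key(all_gap, rm), "")
  other_prefix <- paste(c(rep("A", 14), "C", rep("A", 15)), collapse = "")
  s2 <- pad_seq("TG-CAGGT", prefix = other_prefix) # differs only in FR2
  expect_identical(extract_cdr3j_key(s2, rm), extract_cdr3j_key(s1, rm))
})

test_that("grouping partitions by key and leaves singletons out", {
  keys <- c("AACCGGTT", "AACCGGTT", "AACCGGTT", "CCAAGGTT", "GGAACCTT")
  rep <- toy_repertoire(vapply(keys, pad_seq, character(1)))
  res <- group_by_cdr3j(rep)
  expect_equal(nrow(res$groups), 1)
  expect_equal(res$groups$n_members, 3)
  expect_length(res$singletons, 2)
  all_ids <- sort(c(unlist(res$groups$seq_ids), res$singletons))
  expect_identical(all_ids, sort(rep$sequences$seq_id))
})

test_that("identical junctions in different individuals never share a group", {
  residues <- vapply(rep("AACCGGTT", 4), pad_seq, character(1))
  rep <- toy_repertoire(residues,
                        seq_ids = sprintf("aV1_THY%02d_010116_S%d", 1:4,
                                          c(1, 1, 2, 2)),
                        individual_id = c("S1", "S1", "S2", "S2"))
  res <- group_by_cdr3j(rep)
  expect_equal(nrow(res$groups), 2)
  expect_setequal(res$groups$individual_id, c("S1", "S2"))
})

test_that("grouping is order-independent and keys are byte-identical", {
  cfg <- simulation_config(seed = 21, n_founders = 15)
  sim <- generate_repertoire(cfg)
  res <- group_by_cdr3j(sim$repertoire)
  perm_rep <- sim$repertoire
  set.seed(99)
  perm_rep$sequences <- perm_rep$sequences[sample(nrow(perm_rep$sequences)), ]
  res2 <- group_by_cdr3j(perm_rep)
  canon <- function(r) {
    lapply(r$groups$seq_ids[order(r$groups$cdr3j_key)], sort)
  }
  expect_identical(canon(res), canon(res2))
  expect_identical(sort(res$singletons), sort(res2$singletons))
  for (i in seq_len(nrow(res$groups))) {
    members <- group_members(sim$repertoire, res$groups[i, ])
    rm <- family_region_map(sim$repertoire$regions, res$groups$family_id[i])
    keys <- vapply(members$residues, extract_cdr3j_key, character(1), rm)
    expect_true(all(keys == res$groups$cdr3j_key[i]))
  }
})

test_that("recovered groups equal the simulated founder partition", {
  # zero SHM: exact recovery
  cfg0 <- simulation_config(seed = 31, n_founders = 30, per_base_rate = 0)
  sim0 <- generate_repertoire(cfg0)
  res0 <- group_by_cdr3j(sim0$repertoire)
  truth0 <- split(sim0$truth$lineages$seq_id, sim0$truth$lineages$founder_id)
  truth0 <- unname(lapply(truth0[lengths(truth0) >= 2], sort))
  got0 <- unname(lapply(res0$groups$seq_ids, sort))
  expect_setequal(lapply(got0, paste, collapse = ";"),
                  lapply(truth0, paste, collapse = ";"))
  # default SHM with protected CDR3-J: still exact
  cfg1 <- simulation_config(seed = 32, n_founders = 30)
  sim1 <- generate_repertoire(cfg1)
  res1 <- group_by_cdr3j(sim1$repertoire)
  truth1 <- split(sim1$truth$lineages$seq_id, sim1$truth$lineages$founder_id)
  truth1 <- unname(lapply(truth1[lengths(truth1) >= 2], sort))
  got1 <- unname(lapply(res1$groups$seq_ids, sort))
  expect_setequal(lapply(got1, paste, collapse = ";"),
                  lapply(truth1, paste, collapse = ";"))
  # with CDR3-J mutation allowed, groups + singletons refine the truth
  cfg2 <- simulation_config(seed = 33, n_founders = 30, protect_cdr3j = FALSE)
  sim2 <- generate_repertoire(cfg2)
  res2 <- group_by_cdr3j(sim2$repertoire)
  founder_of <- stats::setNames(sim2$truth$lineages$founder_id,
                                sim2$truth$lineages$seq_id)
  for (ids in res2$groups$seq_ids) {
    expect_length(unique(founder_of[ids]), 1)
  }
})

make_boundary_family <- function() {
  regions <- tibble::tibble(
    family_id = "aV1",
    region_label = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "J", "C"),
    start = as.integer(c(1, 91, 121, 181, 211, 286, 306, 321)),
    end = as.integer(c(90, 120, 180, 210, 285, 305, 320, 330)),
    frame_offset = 1L
  )
  regions
}

test_that("junction boundaries come from cross-individual agreement", {
  regions <- make_boundary_family()
  set.seed(42)
  base <- strsplit(random_dna(330), "", fixed = TRUE)[[1]]
  a <- base; b <- base
  # fully divergent columns 291-300, identical elsewhere
  for (col in 291:300) {
    a[col] <- "A"; b[col] <- "C"
  }
  rep <- toy_repertoire(c(paste(a, collapse = ""), paste(b, collapse = "")),
                        seq_ids = c("aV1_THY01_010116_S1",
                                    "aV1_THY02_010116_S2"),
                        individual_id = c("S1", "S2"), regions = regions)
  bd <- infer_junction_boundaries(rep, "aV1")
  expect_equal(bd$v_last, 290)
  expect_equal(bd$j_first, 301)
})

test_that("identical families fall back to the annotated CDR3 start", {
  regions <- make_boundary_family()
  set.seed(43)
  s <- random_dna(330)
  rep <- toy_repertoire(c(s, s),
                        seq_ids = c("aV1_THY01_010116_S1",
                                    "aV1_THY02_010116_S2"),
                        individual_id = c("S1", "S2"), regions = regions)
  bd <- infer_junction_boundaries(rep, "aV1")
  expect_equal(bd$v_last, 285) # CDR3 start - 1
  expect_equal(bd$j_first, 286)
})

test_that("single-individual families cannot anchor a germline boundary", {
  rep <- toy_repertoire(vapply(c("AACCGGTT", "AACCGGTT"), pad_seq,
                               character(1)))
  expect_error(infer_junction_boundaries(rep, "aV1"),
               "cannot infer germline boundary")
})

test_that("inferred boundaries track simulated trim points", {
  n_fam <- 100
  ok_v <- 0; ok_j <- 0
  for (i in seq_len(n_fam)) {
    cfg <- simulation_config(seed = 1000 + i, n_v_genes = 1, n_j_genes = 1,
                             n_founders = 2, members_per_group = c(1, 1),
                             n_individuals = 2, per_base_rate = 0)
    sim <- generate_repertoire(cfg)
    lay <- sim$locus$layout
    v_end_col <- max(lay$v_tail_cols)
    j_start_col <- min(lay$j_cols)
    lin <- sim$truth$lineages
    truth_v <- v_end_col - max(lin$trim_v)
    truth_j <- j_start_col + max(lin$trim_j)
    bd <- infer_junction_boundaries(sim$repertoire, "aV1")
    if (abs(bd$v_last - truth_v) <= 2) ok_v <- ok_v + 1
    if (abs(bd$j_first - truth_j) <= 2) ok_j <- ok_j + 1
  }
  expect_gte(ok_v / n_fam, 0.9)
  expect_gte(ok_j / n_fam, 0.9)
})

test_that("unique-join counting matches hand-built joins", {
  # CDR3-J content: joins live in cols 31-35 under a fixed boundary
  residues <- c(pad_seq("-----GGT"), pad_seq("A----GGT"),
                pad_seq("A----GGT"), pad_seq("GGT--GGT"))
  rep <- toy_repertoire(residues)
  bd <- list(family_id = "aV1", v_last = 30L, j_first = 36L)
  res <- count_unique_joins(rep, bd)
  expect_equal(res$n_total, 4)
  expect_equal(res$n_unique, 3)
  expect_equal(res$fraction_unique, 0.75)
  expect_equal(res$length_range, c(0L, 3L))
  # all identical
  rep2 <- toy_repertoire(rep(pad_seq("AC---GGT"), 3))
  res2 <- count_unique_joins(rep2, bd)
  expect_equal(res2$fraction_unique, 1 / 3)
})

test_that("junction uniqueness rises with N/P length", {
  fractions <- vapply(list(c(0L, 2L), c(0L, 6L), c(0L, 12L)), function(npr) {
    cfg <- simulation_config(seed = 77, n_v_genes = 1, n_j_genes = 1,
                             n_founders = 200, members_per_group = c(1, 1),
                             np_length = npr, per_base_rate = 0)
    sim <- generate_repertoire(cfg)
    lay <- sim$locus$layout
    bd <- list(family_id = "aV1", v_last = max(lay$v_tail_cols),
               j_first = min(lay$j_cols))
    count_unique_joins(sim$repertoire, bd)$fraction_unique
  }, numeric(1))
  expect_true(all(diff(fractions) > 0))
})

test_that("identity clustering straddles thresholds and is single-linkage", {
  set.seed(7)
  base <- random_dna(100)
  mutate_at <- function(s, cols) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[cols] <- vapply(ch[cols], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  # identical pair
  lab <- assign_families_by_identity(c(base, base))
  expect_identical(lab$label[1], lab$label[2])
  # 87% identity: same family, different subfamilies
  pair <- c(base, mutate_at(base, 1:13))
  lab2 <- assign_families_by_identity(pair)
  expect_equal(lab2$family[1], lab2$family[2])
  expect_false(lab2$subfamily[1] == lab2$subfamily[2])
  # transitive chain: A~B and B~C at 86%, A~C at 72% -> one family
  a <- mutate_at(base, 1:14)
  c_ <- mutate_at(base, 15:28)
  lab3 <- assign_families_by_identity(c(a, base, c_))
  expect_length(unique(lab3$family), 1)
  # brute-force confirmation that A~C alone would not merge
  ident <- function(x, y) {
    mx <- strsplit(x, "")[[1]]; my <- strsplit(y, "")[[1]]
    mean(mx == my)
  }
  expect_lt(ident(a, c_), 0.85)
  expect_gte(ident(a, base), 0.85)
  expect_gte(ident(base, c_), 0.85)
})
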