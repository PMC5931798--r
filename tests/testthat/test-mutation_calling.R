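test_that("consensus takes the plurality base with a first-member tie rule", {
  expect_identical(as.character(build_consensus(c("AAG", "AAG", "AGG"))),
                   "AAG")
  tie <- build_consensus(c("ACG", "GCG"))
  expect_identical(as.character(tie), "ACG") # first member wins the tie
  expect_identical(attr(tie, "tie_columns"), 1L)
  # gap wins only as the strict majority state
  expect_identical(as.character(build_consensus(c("A-", "G-"))), "A-")
  expect_identical(as.character(build_consensus(c("A--", "AG-", "AG-"))),
                   "AG-")
  expect_identical(as.character(build_consensus(c("AG", "A-", "A-"))), "A-")
  expect_error(build_consensus("ACGT"), ">= 2 members")
})

test_that("consensus is invariant under member reordering away from ties", {
  cfg <- simulation_config(seed = 41, n_founders = 6,
                           members_per_group = c(5, 9))
  sim <- generate_repertoire(cfg)
  res <- group_by_cdr3j(sim$repertoire)
  for (i in seq_len(nrow(res$groups))) {
    members <- group_members(sim$repertoire, res$groups[i, ])
    cons <- build_consensus(members$residues)
    set.seed(i)
    cons2 <- build_consensus(sample(members$residues))
    ties <- union(attr(cons, "tie_columns"), attr(cons2, "tie_columns"))
    c1 <- strsplit(as.character(cons), "")[[1]]
    c2 <- strsplit(as.character(cons2), "")[[1]]
    keep <- setdiff(seq_along(c1), ties)
    expect_identical(c1[keep], c2[keep])
  }
})

test_that("nine-member consensus recovers the founder almost everywhere", {
  hits <- 0; total <- 0
  for (r in 1:60) {
    cfg <- simulation_config(seed = 5000 + r, n_founders = 1,
                             members_per_group = c(9, 9))
    sim <- generate_repertoire(cfg)
    f <- strsplit(sim$truth$founders$residues[1], "")[[1]]
    cons <- strsplit(as.character(
      build_consensus(sim$repertoire$sequences$residues)), "")[[1]]
    keep <- which(f != "-")
    hits <- hits + sum(cons[keep] == f[keep])
    total <- total + length(keep)
  }
  expect_gte(hits / total, 0.99)
})

# 41-column toy group helpers
toy_members <- function(residues) {
  tibble::tibble(seq_id = sprintf("aV1_THY%02d_010116_S1",
                                  seq_along(residues)),
                 residues = residues)
}

test_that("calls require both bases present; insertions are excluded", {
  rm <- toy_region_map()
  pad <- function(core) paste0(core, paste(rep("A", 41 - nchar(core)),
                                           collapse = ""))
  cons <- pad("ACG")
  members <- toy_members(c(pad("ACC"), pad("ACG")))
  calls <- call_mutations(members, cons, rm)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$column, 3L)
  expect_identical(calls$consensus_base, "G")
  expect_identical(calls$observed_base, "C")
  expect_identical(calls$region, "FR1")
  # identical member produces nothing
  calls0 <- call_mutations(toy_members(cons), cons, rm)
  expect_equal(nrow(calls0), 0)
  # insertion column: consensus gap, member base -> no call
  cons_gap <- paste0("A-CG", paste(rep("A", 37), collapse = ""))
  mem_ins <- paste0("ATCG", paste(rep("A", 37), collapse = ""))
  expect_equal(nrow(call_mutations(toy_members(c(mem_ins)), cons_gap, rm)), 0)
  # member gap column: no call and a smaller denominator
  mem_gap <- paste0("A-G", substr(cons, 4, 41))
  expect_equal(nrow(call_mutations(toy_members(mem_gap), cons, rm)), 0)
  totals <- region_nucleotide_totals(toy_members(mem_gap), rm)
  expect_equal(totals$total_nucleotides[totals$region == "FR1"], 5L)
})

test_that("single-substitution effects follow the genetic code", {
  # GAT (Asp): third-position C -> GAC (Asp) synonymous
  expect_identical(classify_effect(c("G", "A", "T"), 3L, "C", 1L), "SYN")
  # first-position C -> CAT (His) nonsynonymous
  expect_identical(classify_effect(c("G", "A", "T"), 1L, "C", 1L), "NSYN")
  # tandem GAT -> GCC assessed base by base: A->C NSYN, T->C SYN
  expect_identical(classify_effect(c("G", "A", "T"), 2L, "C", 1L), "NSYN")
  expect_identical(classify_effect(c("G", "A", "T"), 3L, "C", 1L), "SYN")
  # a codon containing a consensus gap cannot be classified
  expect_identical(classify_effect(c("G", "-", "T"), 3L, "C", 1L),
                   "UNDETERMINED")
})

test_that("effect classification agrees with a translation oracle over all codons", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (codon in codons) {
    ch <- strsplit(codon, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, ch[pos])) {
        got <- classify_effect(ch, pos, b, 1L)
        mut <- ch; mut[pos] <- b
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAStringSet(c(codon, paste(mut, collapse = ""))),
          no.init.codon = TRUE))
        expect_identical(got, if (aa[1] == aa[2]) "SYN" else "NSYN")
      }
    }
  }
})

test_that("tandem runs are maximal blocks of consecutive mutated columns", {
  runs <- detect_tandem_runs(c(10L, 11L, 12L, 20L))
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start, 10L)
  expect_equal(runs$length, 3L)
  expect_equal(nrow(detect_tandem_runs(c(5L, 7L))), 0)
  expect_equal(nrow(detect_tandem_runs(integer(0))), 0)
})

test_that("tandem detection matches a brute-force grouping oracle", {
  oracle_runs <- function(cols) {
    cols <- sort(cols)
    out <- list()
    cur <- cols[1]
    for (x in cols[-1]) {
      if (x == cur[length(cur)] + 1) cur <- c(cur, x) else {
        out[[length(out) + 1]] <- cur; cur <- x
      }
    }
    out[[length(out) + 1]] <- cur
    out[lengths(out) >= 2]
  }
  set.seed(101)
  for (i in 1:1000) {
    cols <- sort(sample(100, sample(1:12, 1)))
    got <- detect_tandem_runs(cols)
    want <- oracle_runs(cols)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$start, vapply(want, min, numeric(1)))
      expect_equal(got$length, lengths(want))
    }
  }
})

test_that("call bookkeeping conserves totals per member and per effect", {
  cfg <- simulation_config(seed = 55, n_founders = 12)
  sim <- generate_repertoire(cfg)
  a <- analyze_repertoire(sim$repertoire)
  calls <- a$calls
  # per member: tandem bases + point mutations = total calls
  per_member <- dplyr::count(calls, .data$seq_id)
  tandem <- dplyr::count(calls[!is.na(calls$tandem_run_id), ], .data$seq_id)
  point <- dplyr::count(calls[is.na(calls$tandem_run_id), ], .data$seq_id)
  for (sid in per_member$seq_id) {
    n_t <- tandem$n[tandem$seq_id == sid]
    n_p <- point$n[point$seq_id == sid]
    expect_equal(sum(n_t, n_p), per_member$n[per_member$seq_id == sid])
  }
  # per region and overall: SYN + NSYN + undetermined = total calls
  tab <- region_frequency_table(a)
  expect_true(all(tab$syn + tab$nsyn + tab$undetermined ==
                    tab$total_mutations))
  expect_equal(sum(tab$total_mutations[tab$group_id != "POOLED"]),
               nrow(calls))
})

test_that("the pipeline recovers low and high generative mutation rates", {
  for (r in c(0.005, 0.05)) {
    est <- vapply(1:4, function(k) {
      cfg <- simulation_config(seed = 7000 + 100 * match(r, c(0.005, 0.05)) + k,
                               n_founders = 25, members_per_group = c(4, 4),
                               per_base_rate = r)
      sim <- generate_repertoire(cfg)
      a <- analyze_repertoire(sim$repertoire)
      rc <- region_class_summary(a)
      v <- rc[rc$region_class %in% c("FR", "CDR"), ]
      sum(v$total_mutations) / sum(v$total_nucleotides)
    }, numeric(1))
    expect_lt(abs(stats::median(est) - r) / r, 0.15)
  }
})
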