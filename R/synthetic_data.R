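#' Simulation configuration for synthetic repertoires
#'
#' Defaults emulate the statistical structure of cloned shark TcR-alpha
#' V-region repertoires: germline V genes diversified to ~90% within-family
#' identity, VJ joins shaped by exonuclease trimming and N/P addition (most
#' joins unique), clonal families of 2-9 members, a per-nucleotide mutation
#' rate of 0.02 with ~4-fold G:C targeting to DGYW/WRCH motifs and 2-fold
#' A:T targeting to WA/TW, a 2-fold CDR elevation, transition bias 2:1,
#' tandem runs of 2-4 bases seeded by a quarter of mutation events, and rare
#' in-frame insertions of 3 or 18 nt.
#'
#' @param seed Integer seed; every downstream draw derives from it.
#' @param n_v_genes,n_j_genes Germline segment counts.
#' @param v_length_nt V segment length (multiple of 3, >= 189).
#' @param family_identity Target pairwise nucleotide identity among V genes.
#' @param n_founders Number of founder (naive) rearrangements.
#' @param members_per_group Integer range of clones per founder.
#' @param trim_max Maximum exonuclease trim per side (nt).
#' @param np_length Integer range of total N+P nucleotides per join.
#' @param per_base_rate Marginal per-nucleotide SHM rate over mutable sites.
#' @param gc_hotspot_multiplier,at_hotspot_multiplier Rate multipliers at
#'   DGYW/WRCH G:C targets and WA/TW A:T targets.
#' @param cdr_multiplier Rate multiplier inside CDR1/CDR2 (and CDR3 when
#'   unprotected).
#' @param transition_bias Weight of the transition relative to each
#'   transversion when drawing the substituted base.
#' @param tandem_prob Probability a mutation event extends into a tandem run.
#' @param tandem_max Maximum run length (bases).
#' @param insertion_prob Per-clone probability of an in-frame insertion.
#' @param insertion_lengths Possible insertion lengths (nt, codon multiples).
#' @param n_individuals Number of animals founders are assigned to.
#' @param protect_cdr3j Keep SHM out of CDR3-J columns (default TRUE, so the
#'   clonal-grouping truth is exact).
#' @param j_length_nt,c_length_nt J and C segment lengths (codon multiples).
#' @return A `sim_config` list, validated.
#' @export
simulation_config <- function(seed = 1L,
                              n_v_genes = 6L,
                              n_j_genes = 4L,
                              v_length_nt = 300L,
                              family_identity = 0.9,
                              n_founders = 50L,
                              members_per_group = c(2L, 9L),
                              trim_max = 6L,
                              np_length = c(0L, 12L),
                              per_base_rate = 0.02,
                              gc_hotspot_multiplier = 4.0,
                              at_hotspot_multiplier = 2.0,
                              cdr_multiplier = 2.0,
                              transition_bias = 2.0,
                              tandem_prob = 0.25,
                              tandem_max = 4L,
                              insertion_prob = 0.01,
                              insertion_lengths = c(3L, 18L),
                              n_individuals = 2L,
                              protect_cdr3j = TRUE,
                              j_length_nt = 51L,
                              c_length_nt = 30L) {
  cfg <- as.list(environment())
  stopifnot(v_length_nt %% 3 == 0, v_length_nt >= 189,
            j_length_nt %% 3 == 0, c_length_nt %% 3 == 0,
            all(insertion_lengths %% 3 == 0))
  probs <- c(per_base_rate, tandem_prob, insertion_prob)
  if (any(probs < 0 | probs > 1)) stop("rates/probabilities must lie in [0, 1]")
  if (family_identity < 0 || family_identity > 1) {
    stop("family_identity must lie in [0, 1]")
  }
  mults <- c(gc_hotspot_multiplier, at_hotspot_multiplier, cdr_multiplier,
             transition_bias)
  if (any(mults < 0)) stop("multipliers must be >= 0")
  if (n_founders < 1) stop("n_founders must be >= 1")
  if (members_per_group[1] < 1 || diff(range(members_per_group)) < 0) {
    stop("members_per_group must be a valid positive range")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Fixed alignment layout, IMGT-like: FR1 25, CDR1 8, FR2 17, CDR2 7 codons;
# FR3 absorbs the remaining V length (minus the 9 nt of V that fall inside
# CDR3) plus a reserved 18-column insertion slot; CDR3 = last 9 V nt + the
# join pad; then J and C. All widths are codon multiples except the ragged
# CDR3.
#' @keywords internal
sim_layout <- function(cfg) {
  f3_core <- cfg$v_length_nt - 75 - 24 - 51 - 21 - 9
  ins_w <- max(cfg$insertion_lengths)
  join_w <- max(cfg$np_length)
  fr3_end <- 171 + f3_core + ins_w
  cdr3_end <- fr3_end + 9 + join_w
  j_end <- cdr3_end + cfg$j_length_nt
  c_end <- j_end + cfg$c_length_nt
  list(
    fr1 = c(1, 75), cdr1 = c(76, 99), fr2 = c(100, 150), cdr2 = c(151, 171),
    fr3 = c(172, fr3_end),
    insert_block = c(172 + f3_core, fr3_end),
    cdr3 = c(fr3_end + 1, cdr3_end),
    v_tail_cols = (fr3_end + 1):(fr3_end + 9),
    join_cols = if (join_w > 0) (fr3_end + 10):cdr3_end else integer(0),
    j_cols = (cdr3_end + 1):j_end,
    c_cols = (j_end + 1):c_end,
    aln_length = c_end,
    f3_core = f3_core, ins_w = ins_w, join_w = join_w
  )
}

#' @keywords internal
sim_region_tbl <- function(cfg, family_ids) {
  lay <- sim_layout(cfg)
  one <- tibble::tibble(
    region_label = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "J", "C"),
    start = as.integer(c(lay$fr1[1], lay$cdr1[1], lay$fr2[1], lay$cdr2[1],
                         lay$fr3[1], lay$cdr3[1], min(lay$j_cols),
                         min(lay$c_cols))),
    end = as.integer(c(lay$fr1[2], lay$cdr1[2], lay$fr2[2], lay$cdr2[2],
                       lay$fr3[2], lay$cdr3[2], max(lay$j_cols),
                       max(lay$c_cols))),
    frame_offset = 1L)
  dplyr::bind_rows(lapply(family_ids, function(f) {
    dplyr::mutate(one, family_id = f, .before = 1)
  }))
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

# sample() treats a length-1 numeric vector as 1:n; this never does
#' @keywords internal
sample1 <- function(x) x[sample.int(length(x), 1L)]

#' @keywords internal
random_orf <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' @keywords internal
has_internal_stop <- function(seq) {
  n <- (nchar(seq) %/% 3) * 3
  codons <- substring(seq, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  any(Biostrings::GENETIC_CODE[codons] == "*")
}

#' @keywords internal
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate a germline locus
#'
#' V genes are produced by mutating a random stop-free ancestor so that the
#' expected pairwise identity between genes matches `family_identity` (each
#' gene diverges half the target distance from the ancestor); genes with
#' in-frame stop codons are resampled. J genes and the C segment are
#' independent stop-free open reading frames.
#'
#' @param cfg A `sim_config`. Uses the current RNG state.
#' @return List: `v_genes`, `j_genes` (named character), `c_gene`,
#'   `regions` (region config tibble for families `aV1..aVn`), `layout`.
#' @export
make_germline_locus <- function(cfg) {
  lay <- sim_layout(cfg)
  ancestor <- random_orf(cfg$v_length_nt / 3)
  n_mut <- round((1 - cfg$family_identity) / 2 * cfg$v_length_nt)
  v_genes <- character(cfg$n_v_genes)
  for (k in seq_len(cfg$n_v_genes)) {
    for (attempt in seq_len(100)) {
      ch <- strsplit(ancestor, "", fixed = TRUE)[[1]]
      if (n_mut > 0) {
        pos <- sample(length(ch), n_mut)
        ch[pos] <- vapply(ch[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      cand <- paste(ch, collapse = "")
      if (!has_internal_stop(cand)) break
      cand <- NA_character_
    }
    if (is.na(cand)) {
      stop("could not generate a stop-free V gene at identity ",
           cfg$family_identity)
    }
    v_genes[k] <- cand
  }
  names(v_genes) <- paste0("aV", seq_len(cfg$n_v_genes))
  j_genes <- vapply(seq_len(cfg$n_j_genes), function(k) {
    for (attempt in seq_len(100)) {
      cand <- random_orf(cfg$j_length_nt / 3)
      if (!has_internal_stop(cand)) return(cand)
    }
    stop("could not generate a stop-free J gene")
  }, character(1))
  names(j_genes) <- paste0("J", seq_len(cfg$n_j_genes))
  c_gene <- random_orf(cfg$c_length_nt / 3)
  list(v_genes = v_genes, j_genes = j_genes, c_gene = c_gene,
       regions = sim_region_tbl(cfg, names(v_genes)), layout = lay)
}

#' Simulate one VJ rearrangement
#'
#' Chooses a V and J gene, trims each cut end by Uniform(0, trim_max),
#' inserts a join of N (random) and P (palindromic, <= 2 nt copied from an
#' untrimmed cut end) nucleotides whose total length is drawn from
#' `np_length`, and rejects junctions that are out of frame or create an
#' internal stop codon, resampling until a productive join is found.
#'
#' @param locus From [make_germline_locus()].
#' @param cfg A `sim_config`.
#' @return List: `residues` (aligned founder string), `v_gene`, `j_gene`,
#'   `trim_v`, `trim_j`, `np` (join string).
#' @export
simulate_rearrangement <- function(locus, cfg) {
  lay <- locus$layout
  v_name <- sample1(names(locus$v_genes))
  j_name <- sample1(names(locus$j_genes))
  v_seq <- locus$v_genes[[v_name]]
  j_seq <- locus$j_genes[[j_name]]
  for (attempt in seq_len(200)) {
    trim_v <- sample1(0:cfg$trim_max)
    trim_j <- sample1(0:cfg$trim_max)
    np_total <- sample1(cfg$np_length[1]:cfg$np_length[2])
    if ((np_total - trim_v - trim_j) %% 3 != 0) next
    p_v <- if (trim_v == 0 && np_total > 0) sample1(0:min(2, np_total)) else 0
    p_j <- if (trim_j == 0 && np_total - p_v > 0) {
      sample1(0:min(2, np_total - p_v))
    } else 0
    n_len <- np_total - p_v - p_j
    p_v_str <- if (p_v > 0) {
      revcomp(substr(v_seq, nchar(v_seq) - p_v + 1, nchar(v_seq)))
    } else ""
    p_j_str <- if (p_j > 0) revcomp(substr(j_seq, 1, p_j)) else ""
    n_str <- paste(sample(c("A", "C", "G", "T"), n_len, replace = TRUE),
                   collapse = "")
    join <- paste0(p_v_str, n_str, p_j_str)
    v_kept <- substr(v_seq, 1, nchar(v_seq) - trim_v)
    j_kept <- substr(j_seq, trim_j + 1, nchar(j_seq))
    mrna <- paste0(v_kept, join, j_kept, locus$c_gene)
    if (has_internal_stop(mrna)) next
    return(list(residues = founder_alignment(v_kept, join, j_kept,
                                             locus$c_gene, trim_j, lay),
                v_gene = v_name, j_gene = j_name,
                trim_v = trim_v, trim_j = trim_j, np = join))
  }
  stop("could not produce a productive junction in 200 attempts")
}

# Lay the founder onto fixed alignment columns: germline V occupies its
# columns (trim leaves gaps at the V tail), the join is left-aligned in the
# join pad, the trimmed J is right-anchored at its germline columns, the
# insertion slot stays all-gap.
#' @keywords internal
founder_alignment <- function(v_kept, join, j_kept, c_gene, trim_j, lay) {
  ch <- rep("-", lay$aln_length)
  v_ch <- strsplit(v_kept, "", fixed = TRUE)[[1]]
  v_core_cols <- 1:(171 + lay$f3_core)
  n_core <- length(v_core_cols)
  ch[v_core_cols] <- v_ch[seq_len(n_core)]
  v_tail <- v_ch[-seq_len(n_core)]
  if (length(v_tail) > 0) {
    ch[lay$v_tail_cols[seq_along(v_tail)]] <- v_tail
  }
  if (nchar(join) > 0) {
    ch[lay$join_cols[seq_len(nchar(join))]] <-
      strsplit(join, "", fixed = TRUE)[[1]]
  }
  j_ch <- strsplit(j_kept, "", fixed = TRUE)[[1]]
  ch[lay$j_cols[(trim_j + 1):length(lay$j_cols)]] <- j_ch
  ch[lay$c_cols] <- strsplit(c_gene, "", fixed = TRUE)[[1]]
  paste(ch, collapse = "")
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

#' @keywords internal
draw_substitution <- function(base, transition_bias) {
  alternatives <- setdiff(c("A", "C", "G", "T"), base)
  w <- ifelse(alternatives == TRANSITION_OF[[base]], transition_bias, 1)
  sample(alternatives, 1, prob = w)
}

#' Simulate the SHM descendants of one founder
#'
#' Each descendant first (rarely) acquires an in-frame insertion in the
#' reserved FR3 slot, then undergoes a two-phase mutation process: primary
#' events land with probability proportional to the position weight (hotspot
#' and CDR multipliers over the founder's motif annotation), renormalized so
#' the marginal realized rate over mutable positions — including the bases
#' added by tandem extension — equals `per_base_rate`; each event extends
#' into a rightward tandem run of 2..tandem_max bases with probability
#' `tandem_prob`. Substituted bases are drawn with transition bias. CDR3-J
#' columns are protected by default so the clonal partition stays exact.
#'
#' @param founder From [simulate_rearrangement()].
#' @param locus From [make_germline_locus()].
#' @param cfg A `sim_config`.
#' @param n_members Number of descendants (drawn from `members_per_group`
#'   when NULL).
#' @return List: `residues` (character vector), `mutations` (tibble:
#'   member, column, from_base, to_base, phase, in_hotspot), `insertions`
#'   (tibble: member, start_col, bases).
#' @export
simulate_shm_lineage <- function(founder, locus, cfg, n_members = NULL) {
  lay <- locus$layout
  if (is.null(n_members)) {
    n_members <- sample1(cfg$members_per_group[1]:cfg$members_per_group[2])
  }
  f_ch <- strsplit(founder$residues, "", fixed = TRUE)[[1]]
  ann <- scan_motifs(founder$residues)
  rm <- family_region_map(locus$regions, founder$v_gene)
  region <- region_of_column(rm, seq_along(f_ch))
  protected <- if (cfg$protect_cdr3j) region %in% c("CDR3", "J") else
    rep(FALSE, length(f_ch))
  in_insert_slot <- seq_along(f_ch) %in%
    (lay$insert_block[1]:lay$insert_block[2])
  mutable <- f_ch != "-" & !protected & !in_insert_slot
  w <- rep(0, length(f_ch))
  w[mutable] <- 1
  w[mutable & seq_along(f_ch) %in% ann$gc_targets] <-
    w[mutable & seq_along(f_ch) %in% ann$gc_targets] * cfg$gc_hotspot_multiplier
  w[mutable & seq_along(f_ch) %in% ann$at_targets] <-
    w[mutable & seq_along(f_ch) %in% ann$at_targets] * cfg$at_hotspot_multiplier
  w[mutable & region %in% c("CDR1", "CDR2", "CDR3")] <-
    w[mutable & region %in% c("CDR1", "CDR2", "CDR3")] * cfg$cdr_multiplier
  # Tandem extension onto column c is accepted with probability w[c]/max(w)
  # so the realized marginal per-column rate stays proportional to w (the
  # hotspot/CDR multipliers are defined on per-position rates); the expected
  # bases per event are computed per seed column and folded into the
  # normalization so the marginal rate over mutable sites equals
  # per_base_rate.
  w_max <- if (any(mutable)) max(w[mutable]) else 1
  extra <- expected_tandem_extras(w, mutable, cfg$tandem_prob, cfg$tandem_max,
                                  w_max)
  m_sites <- sum(mutable)
  denom <- sum(w * (1 + extra))
  p <- if (denom > 0) {
    pmin(cfg$per_base_rate * w * m_sites / denom, 0.95)
  } else w
  residues <- character(n_members)
  mutations <- list()
  insertions <- list()
  for (m in seq_len(n_members)) {
    ch <- f_ch
    if (stats::runif(1) < cfg$insertion_prob) {
      len <- sample1(cfg$insertion_lengths)
      ins_cols <- lay$insert_block[1]:(lay$insert_block[1] + len - 1)
      for (attempt in seq_len(50)) {
        bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        ch[ins_cols] <- bases
        if (!has_internal_stop(paste(ch[ch != "-"], collapse = ""))) break
      }
      insertions[[length(insertions) + 1]] <- tibble::tibble(
        member = m, start_col = ins_cols[1],
        bases = paste(bases, collapse = ""))
    }
    hit <- which(stats::runif(length(p)) < p)
    ev_col <- integer(0); ev_from <- character(0); ev_to <- character(0)
    ev_phase <- character(0)
    for (col in hit) {
      run_cols <- col
      if (stats::runif(1) < cfg$tandem_prob && cfg$tandem_max >= 2) {
        run_len <- sample1(2:cfg$tandem_max)
        nxt <- col
        while (length(run_cols) < run_len) {
          nxt <- nxt + 1L
          if (nxt > length(ch) || !mutable[nxt]) break
          if (stats::runif(1) >= w[nxt] / w_max) break
          run_cols <- c(run_cols, nxt)
        }
      }
      for (i in seq_along(run_cols)) {
        cc <- run_cols[i]
        if (ch[cc] == f_ch[cc]) { # skip already-mutated columns
          from <- ch[cc]
          to <- draw_substitution(from, cfg$transition_bias)
          ch[cc] <- to
          ev_col <- c(ev_col, cc)
          ev_from <- c(ev_from, from)
          ev_to <- c(ev_to, to)
          ev_phase <- c(ev_phase, if (i > 1) "tandem_extension" else
            if (from %in% c("G", "C")) "deaminase" else "polymerase_eta")
        }
      }
    }
    if (length(ev_col) > 0) {
      mutations[[length(mutations) + 1]] <- tibble::tibble(
        member = m, column = ev_col, from_base = ev_from, to_base = ev_to,
        phase = ev_phase,
        in_hotspot = ev_col %in% c(ann$gc_targets, ann$at_targets))
    }
    residues[m] <- paste(ch, collapse = "")
  }
  list(residues = residues,
       mutations = dplyr::bind_rows(mutations),
       insertions = dplyr::bind_rows(insertions))
}

# Expected tandem-extension bases per mutation event seeded at each column,
# under uniform run length 2..tandem_max and sequential acceptance
# w[next]/w_max that stops at the first rejection.
#' @keywords internal
expected_tandem_extras <- function(w, mutable, tandem_prob, tandem_max,
                                   w_max) {
  n <- length(w)
  extra <- numeric(n)
  if (tandem_prob <= 0 || tandem_max < 2) return(extra)
  n_lens <- tandem_max - 1
  for (i in which(mutable & w > 0)) {
    acc <- 1
    cum <- numeric(tandem_max - 1) # E[extras | L = k+1] accumulators
    for (k in seq_len(tandem_max - 1)) {
      nxt <- i + k
      if (nxt > n || !mutable[nxt]) break
      acc <- acc * w[nxt] / w_max
      cum[k] <- (if (k > 1) cum[k - 1] else 0) + acc
    }
    # run length L uniform on 2..tandem_max; extras truncated at first break
    for (k in seq_len(tandem_max - 1)) {
      if (k > 1 && cum[k] == 0) cum[k] <- cum[k - 1]
    }
    extra[i] <- tandem_prob * sum(cum) / n_lens
  }
  extra
}

#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed %% 50021L) * 20011 + k * 7919) %% 2147483647)
}

#' Generate a full synthetic repertoire with ground truth
#'
#' Builds a germline locus, simulates `n_founders` rearrangements assigned
#' round-robin to individuals, expands each founder into a clonal lineage
#' under SHM, and returns the repertoire together with a truth log that
#' replays byte-exactly. Each founder consumes its own derived RNG
#' substream, so changing one group's size leaves the others' draws intact.
#'
#' @param cfg A `sim_config`.
#' @return List: `repertoire` (`shm_repertoire`), `truth` (list of tibbles:
#'   `lineages`, `mutations`, `insertions`, `founders`), `locus`.
#' @export
generate_repertoire <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 0L))
  locus <- make_germline_locus(cfg)
  tissues <- c("THY", "PBL", "SPV")
  seqs <- list()
  lineages <- list()
  mutations <- list()
  insertions <- list()
  founders <- list()
  clone_no <- 0L
  for (k in seq_len(cfg$n_founders)) {
    set.seed(derive_seed(cfg$seed, k))
    founder <- simulate_rearrangement(locus, cfg)
    indiv <- paste0("S", (k - 1L) %% cfg$n_individuals + 1L)
    lin <- simulate_shm_lineage(founder, locus, cfg)
    n <- length(lin$residues)
    member_tissue <- sample(tissues, n, replace = TRUE,
                            prob = c(0.6, 0.2, 0.2))
    ids <- character(n)
    for (m in seq_len(n)) {
      clone_no <- clone_no + 1L
      ids[m] <- sprintf("%s_%s%03d_010116_%s", founder$v_gene,
                        member_tissue[m], clone_no, indiv)
    }
    seqs[[k]] <- tibble::tibble(seq_id = ids, family_id = founder$v_gene,
                                tissue = member_tissue, individual_id = indiv,
                                residues = lin$residues)
    lineages[[k]] <- tibble::tibble(
      seq_id = ids, founder_id = paste0("F", k), v_gene = founder$v_gene,
      j_gene = founder$j_gene, trim_v = founder$trim_v,
      trim_j = founder$trim_j, np = founder$np, individual_id = indiv,
      tissue = member_tissue)
    founders[[k]] <- tibble::tibble(founder_id = paste0("F", k),
                                    v_gene = founder$v_gene,
                                    residues = founder$residues)
    if (nrow(lin$mutations) > 0) {
      lin$mutations$seq_id <- ids[lin$mutations$member]
      mutations[[k]] <- lin$mutations[, c("seq_id", "column", "from_base",
                                          "to_base", "phase", "in_hotspot")]
    }
    if (nrow(lin$insertions) > 0) {
      lin$insertions$seq_id <- ids[lin$insertions$member]
      insertions[[k]] <- lin$insertions[, c("seq_id", "start_col", "bases")]
    }
  }
  sequences <- dplyr::bind_rows(seqs)
  rep <- new_shm_repertoire(sequences, locus$regions)
  truth <- list(
    lineages = dplyr::bind_rows(lineages),
    mutations = if (length(mutations) > 0) dplyr::bind_rows(mutations) else
      tibble::tibble(seq_id = character(), column = integer(),
                     from_base = character(), to_base = character(),
                     phase = character(), in_hotspot = logical()),
    insertions = if (length(insertions) > 0) dplyr::bind_rows(insertions) else
      tibble::tibble(seq_id = character(), start_col = integer(),
                     bases = character()),
    founders = dplyr::bind_rows(founders)
  )
  list(repertoire = rep, truth = truth, locus = locus)
}

#' Replay the truth log for one sequence
#'
#' Applies the logged insertion and substitution events to the founder
#' alignment; the result must equal the emitted residues byte-exactly.
#'
#' @param truth Truth list from [generate_repertoire()].
#' @param seq_id Sequence to reconstruct.
#' @return The reconstructed aligned residue string.
#' @export
replay_truth <- function(truth, seq_id) {
  lin <- truth$lineages[truth$lineages$seq_id == seq_id, ]
  if (nrow(lin) != 1) stop("unknown seq_id: ", seq_id)
  f <- truth$founders[truth$founders$founder_id == lin$founder_id, ]
  ch <- strsplit(f$residues, "", fixed = TRUE)[[1]]
  ins <- truth$insertions[truth$insertions$seq_id == seq_id, ]
  for (i in seq_len(nrow(ins))) {
    bases <- strsplit(ins$bases[i], "", fixed = TRUE)[[1]]
    ch[ins$start_col[i] + seq_along(bases) - 1L] <- bases
  }
  mut <- truth$mutations[truth$mutations$seq_id == seq_id, ]
  for (i in seq_len(nrow(mut))) {
    stopifnot(ch[mut$column[i]] == mut$from_base[i])
    ch[mut$column[i]] <- mut$to_base[i]
  }
  paste(ch, collapse = "")
}

#' Generate a dataset on disk
#'
#' Writes `simulated.fasta`, `regions.tsv`, `truth_lineages.tsv`,
#' `truth_mutations.tsv`, `truth_insertions.tsv` and `truth_founders.tsv`.
#' Byte-identical across runs with the same config.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the [generate_repertoire()] result.
#' @export
generate_dataset <- function(cfg, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- generate_repertoire(cfg)
  write_repertoire_fasta(sim$repertoire,
                         file.path(out_dir, "simulated.fasta"),
                         file.path(out_dir, "regions.tsv"))
  readr::write_tsv(sim$truth$lineages, file.path(out_dir, "truth_lineages.tsv"))
  readr::write_tsv(sim$truth$mutations, file.path(out_dir, "truth_mutations.tsv"))
  readr::write_tsv(sim$truth$insertions, file.path(out_dir, "truth_insertions.tsv"))
  readr::write_tsv(sim$truth$founders, file.path(out_dir, "truth_founders.tsv"))
  invisible(sim)
}
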