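#' Build the plurality consensus of a clonal group
#'
#' Per alignment column the consensus takes the most frequent non-gap base
#' among members; the column is a gap only when gaps are the strict majority
#' state (so an insertion carried by a minority of members never enters the
#' consensus). Ties between bases are broken by the first member in input
#' order carrying one of the tied bases; tied columns are recorded.
#'
#' @param residues Character vector of aligned member sequences (>= 2).
#' @return Consensus string, with attributes `tie_columns` (integer vector of
#'   columns where the tie rule fired) and `n_members`.
#' @export
build_consensus <- function(residues) {
  if (length(residues) < 2) stop("a clonal group needs >= 2 members")
  mat <- residue_matrix(residues)
  n_mem <- nrow(mat)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(mat == b),
                   numeric(ncol(mat))) # columns x 4
  n_gap <- n_mem - rowSums(counts)
  top_count <- apply(counts, 1, max)
  n_top <- rowSums(counts == top_count)
  cons <- bases[max.col(counts, ties.method = "first")]
  cons[n_gap > n_mem / 2 | top_count == 0] <- "-"
  ties <- which(n_top > 1 & top_count > 0 & !(n_gap > n_mem / 2))
  for (col in ties) { # rare: break by the first member carrying a tied base
    tied <- bases[counts[col, ] == top_count[col]]
    first_row <- which(mat[, col] %in% tied)[1]
    cons[col] <- mat[first_row, col]
  }
  structure(paste(cons, collapse = ""), tie_columns = as.integer(ties),
            n_members = length(residues))
}

#' Classify a single-base substitution as synonymous or nonsynonymous
#'
#' The observed base is substituted alone into the consensus codon containing
#' the column (its two neighbors stay consensus) and the translated amino
#' acids are compared under the standard genetic code, so each member of a
#' tandem run is assessed independently of its neighbors. A substitution to
#' or from a stop codon is nonsynonymous.
#'
#' @param consensus Consensus string (or its character vector).
#' @param column 1-based alignment column of the substitution; must lie in
#'   the translated interval (FR1 through CDR3).
#' @param observed_base The member's base at that column.
#' @param frame_offset Alignment column of codon position 1 of FR1.
#' @return `"SYN"`, `"NSYN"`, or `"UNDETERMINED"` when the codon contains a
#'   consensus gap (such calls are excluded from SYN/NSYN tallies but still
#'   count toward totals).
#' @export
classify_effect <- function(consensus, column, observed_base, frame_offset) {
  ch <- if (length(consensus) == 1 && nchar(consensus[1]) > 1) {
    strsplit(consensus, "", fixed = TRUE)[[1]]
  } else consensus
  codon_idx <- (column - frame_offset) %/% 3
  cols <- frame_offset + 3L * codon_idx + 0:2
  if (any(cols < 1) || any(cols > length(ch))) return("UNDETERMINED")
  codon <- ch[cols]
  if (any(codon == "-")) return("UNDETERMINED")
  pos <- column - cols[1] + 1L
  mutated <- codon
  mutated[pos] <- observed_base
  aa_ref <- Biostrings::GENETIC_CODE[[paste(codon, collapse = "")]]
  aa_obs <- Biostrings::GENETIC_CODE[[paste(mutated, collapse = "")]]
  if (identical(aa_ref, aa_obs)) "SYN" else "NSYN"
}

#' Call mutations of group members against the consensus
#'
#' One call per (member, column) where the member base differs from the
#' consensus base and both are non-gap. Insertion columns (consensus gap,
#' member base) yield no calls — insertion nucleotides are excluded from
#' mutation counts — and member-gap columns yield no calls and are excluded
#' from that member's denominators. Effects are classified inside the
#' translated FR1..CDR3 interval; J/C substitutions are reported with effect
#' `NA` and tallied separately.
#'
#' @param members Tibble of member sequences (`seq_id`, `residues`), in the
#'   order used for consensus tie-breaking.
#' @param consensus Consensus string from [build_consensus()].
#' @param region_map The family's region map.
#' @return Tibble of calls: seq_id, column, consensus_base, observed_base,
#'   region, effect, base_class, plus tandem run annotation from
#'   [detect_tandem_runs()].
#' @export
call_mutations <- function(members, consensus, region_map) {
  cons_ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  frame_offset <- region_map$frame_offset[1]
  v_cols <- region_columns(region_map, V_REGION_LABELS)
  translated <- seq.int(min(v_cols), max(v_cols))
  calls <- vector("list", nrow(members))
  for (i in seq_len(nrow(members))) {
    ch <- strsplit(members$residues[i], "", fixed = TRUE)[[1]]
    diff_cols <- which(ch != cons_ch & ch != "-" & cons_ch != "-")
    if (length(diff_cols) == 0) next
    effect <- vapply(diff_cols, function(col) {
      if (col %in% translated) {
        classify_effect(cons_ch, col, ch[col], frame_offset)
      } else NA_character_
    }, character(1))
    calls[[i]] <- tibble::tibble(
      seq_id = members$seq_id[i],
      column = as.integer(diff_cols),
      consensus_base = cons_ch[diff_cols],
      observed_base = ch[diff_cols],
      region = region_of_column(region_map, diff_cols),
      effect = effect,
      base_class = ifelse(cons_ch[diff_cols] %in% c("G", "C"), "GC", "AT")
    )
  }
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0) return(empty_call_tbl())
  assign_tandem_ids(calls)
}

#' @keywords internal
empty_call_tbl <- function() {
  tibble::tibble(seq_id = character(), column = integer(),
                 consensus_base = character(), observed_base = character(),
                 region = character(), effect = character(),
                 base_class = character(), tandem_run_id = integer())
}

#' Detect tandem runs among one member's mutated columns
#'
#' A tandem run is a maximal set of >= 2 consecutive mutated alignment
#' columns in one sequence; everything else is a point mutation. A gap column
#' between two mutations separates them (runs never span gaps, since a gap
#' column can never carry a call).
#'
#' @param columns Sorted integer vector of one member's mutated columns.
#' @return Tibble with `run_id`, `start`, `length` for each run (length >= 2).
#' @export
detect_tandem_runs <- function(columns) {
  if (length(columns) == 0) {
    return(tibble::tibble(run_id = integer(), start = integer(),
                          length = integer()))
  }
  columns <- sort(columns)
  grp <- cumsum(c(1L, diff(columns) != 1L))
  lens <- as.integer(table(grp))
  starts <- columns[!duplicated(grp)]
  keep <- lens >= 2
  tibble::tibble(run_id = seq_len(sum(keep)),
                 start = starts[keep], length = lens[keep])
}

#' @keywords internal
assign_tandem_ids <- function(calls) {
  calls$tandem_run_id <- NA_integer_
  next_id <- 1L
  for (sid in unique(calls$seq_id)) {
    rows <- which(calls$seq_id == sid)
    runs <- detect_tandem_runs(calls$column[rows])
    for (k in seq_len(nrow(runs))) {
      span <- runs$start[k]:(runs$start[k] + runs$length[k] - 1L)
      calls$tandem_run_id[rows[calls$column[rows] %in% span]] <- next_id
      next_id <- next_id + 1L
    }
  }
  calls
}

#' Per-member non-gap nucleotide counts by region
#'
#' The denominator convention: a member's gap column reduces its region
#' denominator by one, so totals are "nucleotides actually present in all
#' member sequences" per region.
#'
#' @param members Tibble of member sequences.
#' @param region_map The family's region map.
#' @return Tibble: region, total_nucleotides (summed over members).
#' @export
region_nucleotide_totals <- function(members, region_map) {
  mat <- residue_matrix(members$residues)
  counts <- vapply(seq_len(nrow(region_map)), function(i) {
    cols <- region_map$start[i]:region_map$end[i]
    sum(mat[, cols, drop = FALSE] != "-")
  }, numeric(1))
  tibble::tibble(region = region_map$region_label,
                 total_nucleotides = as.integer(counts))
}
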