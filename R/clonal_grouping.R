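#' Extract the CDR3-J nucleotide key of one sequence
#'
#' The key is the ungapped concatenation of the CDR3 and J alignment columns:
#' every base after the end of the (inferred germline) V segment through the
#' last base of the J segment. Exact nucleotide identity of this key across
#' clones marks descent from a single founder thymocyte, because independent
#' VJ rearrangements essentially never reproduce the same exonuclease
#' trimming and N/P additions.
#'
#' @param residues Aligned residue string of one sequence.
#' @param region_map The sequence's family region map.
#' @return The ungapped CDR3-J nucleotide string (possibly empty).
#' @export
extract_cdr3j_key <- function(residues, region_map) {
  cols <- region_columns(region_map, c("CDR3", "J"))
  ch <- strsplit(residues, "", fixed = TRUE)[[1]][cols]
  paste(ch[ch != "-"], collapse = "")
}

#' @keywords internal
region_columns <- function(region_map, labels) {
  rows <- region_map[region_map$region_label %in% labels, ]
  unlist(lapply(seq_len(nrow(rows)), function(i) rows$start[i]:rows$end[i]),
         use.names = FALSE)
}

#' Group sequences into clonal families by exact CDR3-J identity
#'
#' Partitions a repertoire on the key (family, CDR3-J string, individual).
#' Identity is required at the nucleotide level over the entire CDR3-J
#' interval; the individual is part of the key because the same junction in
#' two animals cannot share a founder cell.
#'
#' @param rep An `shm_repertoire`.
#' @param min_size Minimum group size (default 2); smaller sets are returned
#'   as singletons.
#' @return List with `groups` (tibble: group_id, family_id, individual_id,
#'   n_members, cdr3j_key, seq_ids list-column, sorted by family then
#'   descending size) and `singletons` (character vector of seq_ids).
#' @export
group_by_cdr3j <- function(rep, min_size = 2) {
  seqs <- rep$sequences
  if (nrow(seqs) == 0) {
    return(list(groups = empty_group_tbl(), singletons = character(0)))
  }
  keys <- vapply(seq_len(nrow(seqs)), function(i) {
    extract_cdr3j_key(seqs$residues[i],
                      family_region_map(rep$regions, seqs$family_id[i]))
  }, character(1))
  df <- tibble::tibble(seq_id = seqs$seq_id, family_id = seqs$family_id,
                       individual_id = seqs$individual_id, key = keys)
  # deterministic partition regardless of input order
  grouped <- dplyr::group_by(df, .data$family_id, .data$key, .data$individual_id)
  parts <- dplyr::summarise(grouped,
                            n_members = dplyr::n(),
                            seq_ids = list(sort(.data$seq_id)),
                            .groups = "drop")
  big <- parts[parts$n_members >= min_size, ]
  big <- big[order(big$family_id, -big$n_members,
                   vapply(big$seq_ids, `[`, character(1), 1)), ]
  if (nrow(big) > 0) {
    idx <- stats::ave(seq_len(nrow(big)), big$family_id, FUN = seq_along)
    group_id <- paste0(big$family_id, ".", idx)
  } else {
    group_id <- character(0)
  }
  groups <- tibble::tibble(group_id = group_id,
                           family_id = big$family_id,
                           individual_id = big$individual_id,
                           n_members = big$n_members,
                           cdr3j_key = big$key,
                           seq_ids = big$seq_ids)
  singles <- sort(unlist(parts$seq_ids[parts$n_members < min_size]))
  if (is.null(singles)) singles <- character(0)
  list(groups = groups, singletons = singles)
}

#' Group sequences by a known lineage partition
#'
#' Alternative to [group_by_cdr3j()] when the founder of every sequence is
#' known (simulated data, or external lineage calls): groups are the founder
#' partition, with the CDR3-J key of the first member recorded for
#' reference.
#'
#' @param rep An `shm_repertoire`.
#' @param lineages Tibble with `seq_id` and `founder_id`.
#' @param min_size Minimum group size.
#' @return Same shape as [group_by_cdr3j()].
#' @export
group_by_lineage <- function(rep, lineages, min_size = 2) {
  seqs <- rep$sequences
  founder <- lineages$founder_id[match(seqs$seq_id, lineages$seq_id)]
  if (anyNA(founder)) stop("lineages must cover every sequence")
  parts <- split(seq_len(nrow(seqs)), founder)
  sizes <- lengths(parts)
  big <- parts[sizes >= min_size]
  ord <- order(vapply(big, function(i) seqs$family_id[i[1]], character(1)),
               -lengths(big))
  big <- big[ord]
  groups <- tibble::tibble(
    group_id = names(big),
    family_id = vapply(big, function(i) seqs$family_id[i[1]], character(1)),
    individual_id = vapply(big, function(i) seqs$individual_id[i[1]],
                           character(1)),
    n_members = lengths(big),
    cdr3j_key = vapply(big, function(i) {
      extract_cdr3j_key(seqs$residues[i[1]],
                        family_region_map(rep$regions, seqs$family_id[i[1]]))
    }, character(1)),
    seq_ids = lapply(big, function(i) sort(seqs$seq_id[i]))
  )
  singles <- sort(unlist(lapply(parts[sizes < min_size],
                                function(i) seqs$seq_id[i])))
  if (is.null(singles)) singles <- character(0)
  list(groups = groups, singletons = unname(singles))
}

#' @keywords internal
empty_group_tbl <- function() {
  tibble::tibble(group_id = character(), family_id = character(),
                 individual_id = character(), n_members = integer(),
                 cdr3j_key = character(), seq_ids = list())
}

#' Subset the member sequences of one clonal group
#' @param rep An `shm_repertoire`.
#' @param group One row of the `groups` tibble.
#' @return Tibble of member sequences, in `seq_ids` order.
#' @export
group_members <- function(rep, group) {
  ids <- group$seq_ids[[1]]
  rep$sequences[match(ids, rep$sequences$seq_id), ]
}

#' Infer germline V/J boundaries from cross-individual agreement
#'
#' Any nucleotide observed at the same alignment column in more than one
#' individual is taken to be germline (two animals will not independently
#' draw the same non-templated base, except by rare coincidence). Scanning
#' 5'→3' from FR1, the germline V extension ends when a run of
#' `break_threshold` consecutive columns lacks any cross-individual shared
#' base; the J start is found symmetrically scanning 3'→5' from the J end.
#'
#' @param rep An `shm_repertoire`.
#' @param family_id Family to analyze; requires >= 2 individuals.
#' @param break_threshold Consecutive no-agreement columns that terminate the
#'   germline extension (default 2, so a lone polymorphism does not end it).
#' @return List with `family_id`, `v_last` (last inferred germline V column,
#'   1-based) and `j_first` (first inferred germline J column). If the family
#'   is identical across its whole length the region map's CDR3 start is used
#'   as the fallback boundary on both sides.
#' @export
infer_junction_boundaries <- function(rep, family_id, break_threshold = 2) {
  seqs <- rep$sequences[rep$sequences$family_id == family_id, ]
  if (length(unique(seqs$individual_id)) < 2) {
    stop("cannot infer germline boundary: family ", family_id,
         " has sequences from fewer than 2 individuals")
  }
  rm <- family_region_map(rep$regions, family_id)
  mat <- residue_matrix(seqs$residues)
  indiv <- seqs$individual_id
  first_col <- min(rm$start[rm$region_label == "FR1"])
  last_col <- max(rm$end[rm$region_label == "J"])
  # per column: 1 = cross-individual shared base, 0 = all-gap
  # (uninformative), -1 = bases present but none shared
  agree <- vapply(first_col:last_col, function(col) {
    column_agreement_state(mat[, col], indiv)
  }, integer(1))
  cdr3_start <- rm$start[rm$region_label == "CDR3"]

  v_last <- scan_boundary(agree, break_threshold)
  if (is.na(v_last)) {
    # identical across the family: fall back to the annotated CDR3 start
    return(list(family_id = family_id, v_last = cdr3_start - 1L,
                j_first = cdr3_start))
  }
  v_last <- first_col - 1L + v_last
  j_rel <- scan_boundary(rev(agree), break_threshold)
  j_first <- if (is.na(j_rel)) cdr3_start else last_col + 1L - j_rel
  if (j_first <= v_last) {
    warning("family ", family_id,
            ": inferred V and J germline extents overlap; clamping")
    j_first <- v_last + 1L
  }
  list(family_id = family_id, v_last = as.integer(v_last),
       j_first = as.integer(j_first))
}

# Position (1-based, within the scanned vector) of the last agreeing column
# seen before a mismatch run of length >= threshold; NA if no such run.
# All-gap columns are uninformative: they neither extend agreement nor count
# toward the mismatch run.
#' @keywords internal
scan_boundary <- function(agree, threshold) {
  run <- 0L
  last_ok <- 0L
  for (i in seq_along(agree)) {
    if (agree[i] > 0L) {
      run <- 0L
      last_ok <- i
    } else if (agree[i] < 0L) {
      run <- run + 1L
      if (run >= threshold) return(last_ok)
    }
  }
  NA_integer_
}

#' @keywords internal
column_agreement_state <- function(bases, indiv) {
  keep <- bases != "-"
  if (!any(keep)) return(0L)
  pairs <- unique(data.frame(base = bases[keep], indiv = indiv[keep]))
  if (any(table(pairs$base) >= 2)) 1L else -1L
}

#' @keywords internal
residue_matrix <- function(residues) {
  do.call(rbind, strsplit(residues, "", fixed = TRUE))
}

#' Count unique V-J join strings
#'
#' The join of a sequence is the ungapped string between the inferred
#' germline V end and germline J start: the exonuclease-trimmed, N/P-filled
#' junction. Uniqueness is exact string equality.
#'
#' @param rep An `shm_repertoire`.
#' @param boundary A junction boundary as from [infer_junction_boundaries()].
#' @param seq_ids Optional subset of sequences to count (default: all of the
#'   boundary's family).
#' @return List with `n_total`, `n_unique`, `fraction_unique`,
#'   `length_range` (min, max join length in nt) and the `joins` themselves.
#' @export
count_unique_joins <- function(rep, boundary, seq_ids = NULL) {
  seqs <- rep$sequences[rep$sequences$family_id == boundary$family_id, ]
  if (!is.null(seq_ids)) seqs <- seqs[seqs$seq_id %in% seq_ids, ]
  cols <- seq.int(boundary$v_last + 1L, boundary$j_first - 1L)
  if (boundary$j_first - boundary$v_last <= 1L) cols <- integer(0)
  joins <- vapply(seqs$residues, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]][cols]
    paste(ch[ch != "-"], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  lens <- nchar(joins)
  list(n_total = length(joins),
       n_unique = length(unique(joins)),
       fraction_unique = if (length(joins) > 0) length(unique(joins)) / length(joins) else NA_real_,
       length_range = if (length(joins) > 0) c(min(lens), max(lens)) else c(NA_integer_, NA_integer_),
       joins = joins)
}

#' Cluster sequences into V families/subfamilies by nucleotide identity
#'
#' Single-linkage clustering on pairwise identity, computed over aligned
#' columns where both sequences are ungapped (matches / comparable columns).
#' Sequences joined at >= the family threshold share a family; at >= the
#' subfamily threshold, a subfamily. Labels are deterministic: numbered by
#' first occurrence in input order. Single linkage approximates tree-based
#' family assignment mechanically (a transitive chain of near-identical
#' sequences is one family even if its extremes diverge).
#'
#' @param residues Character vector of aligned, equal-length sequences.
#' @param thresholds Named numeric: `family` (default 0.85) and `subfamily`
#'   (default 0.90) identity cutoffs.
#' @return Tibble with `family` and `subfamily` integer labels plus a
#'   `label` like "F2.1" (family 2, subfamily 1 within it).
#' @export
assign_families_by_identity <- function(residues,
                                        thresholds = c(family = 0.85,
                                                       subfamily = 0.90)) {
  n <- length(residues)
  if (n == 0) {
    return(tibble::tibble(family = integer(), subfamily = integer(),
                          label = character()))
  }
  if (length(unique(nchar(residues))) != 1) {
    stop("sequences must be aligned to equal length")
  }
  if (n == 1) {
    return(tibble::tibble(family = 1L, subfamily = 1L, label = "F1.1"))
  }
  mat <- residue_matrix(residues)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      ident <- if (any(ok)) sum(mat[i, ok] == mat[j, ok]) / sum(ok) else 0
      d[i, j] <- d[j, i] <- 1 - ident
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  fam <- relabel_first_seen(stats::cutree(hc, h = 1 - thresholds[["family"]] + 1e-9))
  sub <- relabel_first_seen(stats::cutree(hc, h = 1 - thresholds[["subfamily"]] + 1e-9))
  sub_within <- integer(n)
  for (f in unique(fam)) {
    sub_within[fam == f] <- relabel_first_seen(sub[fam == f])
  }
  tibble::tibble(family = fam, subfamily = sub_within,
                 label = paste0("F", fam, ".", sub_within))
}

#' @keywords internal
relabel_first_seen <- function(labels) {
  as.integer(match(labels, unique(labels)))
}
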