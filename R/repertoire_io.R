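#' Read a region-annotation configuration
#'
#' A region config assigns every V family in an alignment its framework (FR),
#' complementarity-determining (CDR), joining (J) and constant (C) intervals,
#' plus the alignment column at which codon position 1 of FR1 sits. All
#' coordinates are 1-based inclusive alignment columns.
#'
#' @param path Path to a TSV with columns `family_id`, `region_label`,
#'   `start`, `end`, `frame_offset`.
#' @return A tibble with one row per (family, region), validated so that for
#'   every family the FR1..CDR3 intervals tile the V region contiguously
#'   without overlap.
#' @export
read_region_config <- function(path) {
  regions <- readr::read_tsv(path, col_types = readr::cols(
    family_id = readr::col_character(),
    region_label = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    frame_offset = readr::col_integer()
  ))
  validate_region_config(regions)
  regions
}

REGION_LABELS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "J", "C")
V_REGION_LABELS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3")

#' @keywords internal
validate_region_config <- function(regions) {
  required <- c("family_id", "region_label", "start", "end", "frame_offset")
  missing <- setdiff(required, names(regions))
  if (length(missing) > 0) {
    stop("region config missing columns: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(regions$region_label), REGION_LABELS)
  if (length(bad) > 0) {
    stop("unknown region labels: ", paste(bad, collapse = ", "))
  }
  for (fam in unique(regions$family_id)) {
    rm <- regions[regions$family_id == fam, ]
    if (any(rm$end < rm$start)) {
      stop("family ", fam, ": region with end < start")
    }
    v <- rm[match(V_REGION_LABELS, rm$region_label), ]
    if (anyNA(v$region_label)) {
      stop("family ", fam, ": missing V-region intervals (need FR1..CDR3)")
    }
    # FR1..CDR3 must tile the V interval contiguously
    if (any(v$start[-1] != v$end[-length(V_REGION_LABELS)] + 1)) {
      stop("family ", fam, ": FR/CDR intervals do not tile contiguously")
    }
    fr_cdr <- v[v$region_label != "CDR3", ]
    if (any((fr_cdr$end - fr_cdr$start + 1) %% 3 != 0)) {
      stop("family ", fam, ": FR/CDR1/CDR2 lengths must be codon multiples")
    }
    off <- unique(rm$frame_offset)
    if (length(off) != 1 || !off %in% (v$start[1] + 0:2)) {
      stop("family ", fam, ": frame_offset must be a single value within FR1 start..start+2")
    }
  }
  invisible(regions)
}

#' Retrieve one family's region map
#' @param regions Region config tibble.
#' @param family_id Family identifier.
#' @return Tibble of intervals for that family, ordered FR1..C.
#' @export
family_region_map <- function(regions, family_id) {
  rm <- regions[regions$family_id == family_id, ]
  if (nrow(rm) == 0) stop("no region map for family '", family_id, "'")
  rm[order(rm$start), ]
}

#' Map alignment columns to region labels
#'
#' @param region_map A single family's region map.
#' @param columns Integer vector of 1-based alignment columns.
#' @return Character vector of region labels (NA outside all intervals).
#' @export
region_of_column <- function(region_map, columns) {
  out <- rep(NA_character_, length(columns))
  for (i in seq_len(nrow(region_map))) {
    hit <- columns >= region_map$start[i] & columns <= region_map$end[i]
    out[hit] <- region_map$region_label[i]
  }
  out
}

#' Parse tissue and individual metadata from sequence identifiers
#'
#' Identifiers follow `<family>[._]<TISSUE><clone>_<date>[_<individual>]`,
#' e.g. `aV7.2_THY09_051410` or `aV1_SPV03_010116_S2`. The family is the
#' token before the first underscore; the tissue code is the leading letters
#' of the second token (THY, PBL, SPV, SPL); anything unrecognized maps to
#' OTHER with a warning, never an error.
#'
#' @param seq_ids Character vector of identifiers.
#' @return Tibble with `seq_id`, `family_id`, `tissue`, `individual_id`.
#' @export
parse_seq_metadata <- function(seq_ids) {
  tokens <- strsplit(seq_ids, "_", fixed = TRUE)
  family <- vapply(tokens, function(x) x[1], character(1))
  tissue_tok <- vapply(tokens, function(x) if (length(x) >= 2) x[2] else "", character(1))
  code <- toupper(stringr::str_extract(tissue_tok, "^[A-Za-z]+"))
  tissue <- dplyr::case_when(
    code %in% "THY" ~ "THY",
    code %in% "PBL" ~ "PBL",
    code %in% "SPV" ~ "SPV",
    code %in% c("SPL", "SPLEEN") ~ "SPLEEN",
    TRUE ~ "OTHER"
  )
  if (any(tissue == "OTHER")) {
    warning("could not parse tissue for ",
            sum(tissue == "OTHER"), " sequence id(s); assigned OTHER")
  }
  individual <- vapply(tokens, function(x) {
    if (length(x) >= 4) x[length(x)] else "unknown"
  }, character(1))
  tibble::tibble(seq_id = seq_ids, family_id = family,
                 tissue = tissue, individual_id = individual)
}

#' Read an annotated, pre-aligned repertoire
#'
#' Reads a gapped multi-FASTA of cloned V-region cDNA sequences together with
#' a region config. Sequences are assumed pre-aligned within each family;
#' this package never re-aligns. Residues are uppercased; gaps (`-`) are
#' preserved; any character outside `A/C/G/T/-` is a hard error reporting the
#' offending column.
#'
#' @param fasta_path Path to the multi-FASTA.
#' @param regions Either a path to a region config TSV or a region tibble.
#' @return An object of class `shm_repertoire`: a list with `$sequences`
#'   (tibble: seq_id, family_id, tissue, individual_id, residues) and
#'   `$regions` (the region config).
#' @export
read_annotated_fasta <- function(fasta_path, regions) {
  if (is.character(regions)) regions <- read_region_config(regions)
  validate_region_config(regions)
  recs <- Biostrings::readBStringSet(fasta_path)
  if (length(recs) == 0) {
    warning("empty FASTA: ", fasta_path)
    return(new_shm_repertoire(empty_sequence_tbl(), regions))
  }
  residues <- toupper(as.character(recs))
  ids <- names(recs)
  for (i in seq_along(residues)) {
    ch <- strsplit(residues[i], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% c("A", "C", "G", "T", "-"))
    if (length(bad) > 0) {
      stop("sequence '", ids[i], "': non-ACGT/gap character '",
           ch[bad[1]], "' at column ", bad[1])
    }
  }
  meta <- parse_seq_metadata(ids)
  seqs <- dplyr::mutate(meta, residues = unname(residues))
  missing_fams <- setdiff(unique(seqs$family_id), unique(regions$family_id))
  if (length(missing_fams) > 0) {
    stop("no region map for family: ", paste(missing_fams, collapse = ", "))
  }
  rep <- new_shm_repertoire(seqs, regions)
  validate_repertoire(rep)
  rep
}

#' @keywords internal
empty_sequence_tbl <- function() {
  tibble::tibble(seq_id = character(), family_id = character(),
                 tissue = character(), individual_id = character(),
                 residues = character())
}

#' @keywords internal
new_shm_repertoire <- function(sequences, regions) {
  structure(list(sequences = sequences, regions = regions),
            class = "shm_repertoire")
}

#' @keywords internal
validate_repertoire <- function(rep) {
  seqs <- rep$sequences
  for (fam in unique(seqs$family_id)) {
    rm <- family_region_map(rep$regions, fam)
    lens <- nchar(seqs$residues[seqs$family_id == fam])
    if (length(unique(lens)) > 1) {
      stop("family ", fam, ": members have unequal alignment lengths")
    }
    if (lens[1] < max(rm$end)) {
      stop("family ", fam, ": alignment length ", lens[1],
           " shorter than region map end ", max(rm$end))
    }
  }
  invisible(rep)
}

#' @export
print.shm_repertoire <- function(x, ...) {
  cat("<shm_repertoire> ", nrow(x$sequences), " sequences, ",
      length(unique(x$sequences$family_id)), " families\n", sep = "")
  invisible(x)
}

#' Write a repertoire back to FASTA (+ region TSV)
#'
#' Inverse of [read_annotated_fasta()]; used by the simulator and for
#' round-trip checks.
#'
#' @param rep An `shm_repertoire`.
#' @param fasta_path Output FASTA path.
#' @param regions_path Optional output TSV path for the region config.
#' @return Invisibly, the paths written.
#' @export
write_repertoire_fasta <- function(rep, fasta_path, regions_path = NULL) {
  set <- Biostrings::BStringSet(rep$sequences$residues)
  names(set) <- rep$sequences$seq_id
  Biostrings::writeXStringSet(set, fasta_path, width = 80)
  paths <- fasta_path
  if (!is.null(regions_path)) {
    readr::write_tsv(rep$regions, regions_path)
    paths <- c(paths, regions_path)
  }
  invisible(paths)
}

#' Write report tables as TSVs
#'
#' Emits one TSV per summary table (region frequencies, tandem mutations,
#' mutability indices, hotspot enrichment, tissue stratification) plus a
#' `summary.json` of headline numbers. Frequencies are percentages to two
#' decimals and mutability indices to two decimals in the files; underlying
#' tibbles keep full precision. Rerunning into the same directory overwrites
#' deterministically.
#'
#' @param tables Named list of tibbles (as produced by [report_tables()]).
#' @param out_dir Output directory (created if absent).
#' @param summary Optional named list written as `summary.json`.
#' @return Character vector of file paths written.
#' @export
write_report_tables <- function(tables, out_dir, summary = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- format_report_numbers(tables[[nm]])
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tab, path)
    paths <- c(paths, path)
  }
  if (!is.null(summary)) {
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, path)
  }
  paths
}

#' @keywords internal
format_report_numbers <- function(tab) {
  two_dp <- grepl("freq|pct|mutability_index|probability|expected", names(tab))
  for (j in which(two_dp)) {
    if (is.numeric(tab[[j]])) tab[[j]] <- round(tab[[j]], 2)
  }
  tab
}
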