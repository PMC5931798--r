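#' Run the full SHM analysis on a repertoire
#'
#' Orchestrates clonal grouping by exact CDR3-J identity, per-group consensus
#' building, mutation calling with SYN/NSYN classification and tandem-run
#' detection, hotspot-motif scanning, and the per-group nucleotide
#' bookkeeping every summary table needs. Deterministic: rerunning on
#' identical inputs yields identical results.
#'
#' @param rep An `shm_repertoire` from [read_annotated_fasta()].
#' @param min_size Minimum clonal group size (default 2).
#' @param lineages Optional tibble with `seq_id` and `founder_id` columns
#'   (e.g. a simulator truth log): when supplied, clonal groups are taken
#'   from the known lineage partition instead of CDR3-J identity. Useful for
#'   calibration studies where the conservative identical-junction grouping
#'   would censor junction-region mutations.
#' @return An object of class `shm_analysis`: list with `repertoire`,
#'   `groups`, `singletons`, `consensus` (named list of strings),
#'   `annotations` (named list of hotspot annotations), `calls` (one tibble,
#'   `group_id` column), `target_counts` (per-group class/stratum nucleotide
#'   totals) and `region_totals` (per-group region denominators). If no
#'   group reaches `min_size` a warning is raised and the object carries
#'   empty tables.
#' @export
analyze_repertoire <- function(rep, min_size = 2, lineages = NULL) {
  grouping <- if (is.null(lineages)) {
    group_by_cdr3j(rep, min_size = min_size)
  } else {
    group_by_lineage(rep, lineages, min_size = min_size)
  }
  groups <- grouping$groups
  consensus <- list()
  annotations <- list()
  calls <- list()
  target_counts <- list()
  region_totals <- list()
  for (i in seq_len(nrow(groups))) {
    grp <- groups[i, ]
    gid <- grp$group_id
    members <- group_members(rep, grp)
    rm <- family_region_map(rep$regions, grp$family_id)
    cons <- build_consensus(members$residues)
    ann <- scan_motifs(cons)
    grp_calls <- call_mutations(members, cons, rm)
    grp_calls <- annotate_hotspot_calls(grp_calls, ann)
    grp_calls$group_id <- gid
    tc <- count_targets_by_region(ann, cons, members, rm)
    tc$group_id <- gid
    rt <- region_nucleotide_totals(members, rm)
    rt$group_id <- gid
    rt$n_sequences <- nrow(members)
    consensus[[gid]] <- as.character(cons)
    annotations[[gid]] <- ann
    calls[[gid]] <- grp_calls
    target_counts[[gid]] <- tc
    region_totals[[gid]] <- rt
  }
  if (nrow(groups) == 0) {
    warning("no clonal group of size >= ", min_size, "; analysis is empty")
  }
  calls <- if (length(calls) > 0) dplyr::bind_rows(calls) else
    dplyr::mutate(empty_call_tbl(), in_hotspot = logical(0),
                  motif = character(0), group_id = character(0))
  structure(list(
    repertoire = rep,
    groups = groups,
    singletons = grouping$singletons,
    consensus = consensus,
    annotations = annotations,
    calls = calls,
    target_counts = dplyr::bind_rows(target_counts),
    region_totals = dplyr::bind_rows(region_totals)
  ), class = "shm_analysis")
}

#' @export
print.shm_analysis <- function(x, ...) {
  cat("<shm_analysis> ", nrow(x$groups), " clonal groups, ",
      length(x$singletons), " singletons, ", nrow(x$calls),
      " mutation calls\n", sep = "")
  invisible(x)
}

#' Assemble all report tables and headline numbers
#'
#' @param analysis An `shm_analysis`.
#' @return List with `tables` (named list of tibbles: groups, mutations,
#'   region_freq, tandem, mutability, hotspots, tissue) and `summary`
#'   (named list of headline numbers for `summary.json`).
#' @export
report_tables <- function(analysis) {
  groups_tab <- analysis$groups
  groups_tab$member_seq_ids <- vapply(groups_tab$seq_ids, paste,
                                      character(1), collapse = ";")
  groups_tab <- groups_tab[, c("group_id", "family_id", "individual_id",
                               "n_members", "cdr3j_key", "member_seq_ids")]
  mut_tab <- analysis$calls
  if (nrow(mut_tab) > 0) {
    mut_tab <- mut_tab[, c("group_id", "seq_id", "column", "region",
                           "consensus_base", "observed_base", "effect",
                           "motif", "tandem_run_id")]
  }
  empty <- nrow(analysis$groups) == 0
  region_tab <- region_frequency_table_or_empty(analysis)
  tandem_tab <- if (empty) empty_totals("tandem") else tandem_table(analysis)
  mutab <- if (empty) empty_totals("mutability") else
    mutability_from_analysis(analysis, "ALL")
  hot <- if (empty) empty_totals("hotspots") else
    hotspot_enrichment_table(analysis)
  tissue <- if (empty) list(table = empty_totals("tissue"),
                            tests = tibble::tibble()) else
    withCallingHandlers(tissue_stratified_table(analysis),
                        warning = function(w) invokeRestart("muffleWarning"))
  spectrum <- substitution_spectrum(analysis$calls)
  summary <- list(
    n_groups = nrow(analysis$groups),
    n_singletons = length(analysis$singletons),
    n_mutations = nrow(analysis$calls)
  )
  if (!empty) {
    rc <- region_class_summary(analysis)
    pick <- function(cls, col) {
      v <- rc[[col]][rc$region_class == cls]
      if (length(v) == 0) NA_real_ else v
    }
    v_nt <- sum(rc$total_nucleotides[rc$region_class %in% c("FR", "CDR")])
    v_mut <- sum(rc$total_mutations[rc$region_class %in% c("FR", "CDR")])
    hot_gc <- hot[hot$base_class == "GC" & hot$stratum == "ALL", ]
    summary <- c(summary, list(
      overall_frequency = if (v_nt > 0) v_mut / v_nt else NA_real_,
      fr_frequency = pick("FR", "freq"),
      cdr_frequency = pick("CDR", "freq"),
      gc_enrichment_ratio = hot_gc$enrichment_ratio,
      transition_pct = spectrum$transition_pct,
      gc_mutation_pct = spectrum$gc_mutation_pct,
      tandem_fr_pct = tandem_tab$tandem_freq_pct[
        tandem_tab$group_id == "TOTAL" & tandem_tab$region_class == "FR"],
      tandem_cdr_pct = tandem_tab$tandem_freq_pct[
        tandem_tab$group_id == "TOTAL" & tandem_tab$region_class == "CDR"],
      mutability_index = stats::setNames(
        as.list(mutab$mutability_index[match(c("G", "C", "A", "T"),
                                             mutab$base)]),
        c("G", "C", "A", "T"))
    ))
  }
  list(tables = list(groups = groups_tab, mutations = mut_tab,
                     region_freq = region_tab, tandem = tandem_tab,
                     mutability = mutab, hotspots = hot,
                     tissue = tissue$table),
       tissue_tests = tissue$tests,
       summary = summary)
}

#' @keywords internal
region_frequency_table_or_empty <- function(analysis) {
  if (nrow(analysis$groups) == 0) return(empty_totals("region_freq"))
  region_frequency_table(analysis)
}

# A minimal all-zero totals table so empty analyses still write valid files.
#' @keywords internal
empty_totals <- function(kind) {
  tibble::tibble(group_id = "TOTAL", kind = kind, total_nucleotides = 0L,
                 total_mutations = 0L, freq_pct = 0)
}

#' Analyze a repertoire and write the report bundle
#'
#' Thin end-to-end wrapper: [analyze_repertoire()], [report_tables()],
#' [write_report_tables()].
#'
#' @param rep An `shm_repertoire`.
#' @param out_dir Output directory.
#' @param min_size Minimum group size.
#' @return Invisibly, the `shm_analysis`.
#' @export
run_shm_report <- function(rep, out_dir, min_size = 2) {
  analysis <- analyze_repertoire(rep, min_size = min_size)
  bundle <- report_tables(analysis)
  write_report_tables(bundle$tables, out_dir, summary = bundle$summary)
  invisible(analysis)
}
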