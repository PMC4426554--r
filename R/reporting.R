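# Pipeline wrappers and report rendering: one function per pipeline
# stage, each reading raw files and writing JSON/TSV/text reports.
# The thin command-line entry point in inst/cli/ddicompare dispatches
# to these.

read_source_file <- function(type, path) {
  # a name may carry a distinguishing suffix, e.g. "NDFRT.2014"
  type <- sub("[._].*$", "", toupper(type))
  switch(type,
         NDFRT = read_ndfrt_records(path),
         DRUGBANK = read_drugbank_xml(path),
         ddi_stop("ddi_contract_error", "unknown source type: %s", type))
}

#' Normalize raw source files and write reports
#'
#' Ingests each raw source file, normalizes it against the terminology,
#' and writes a normalized-pair TSV plus an audit-report JSON per
#' source.
#'
#' @param concept_file,relation_file,atc_file Terminology bundle paths
#'   (see [load_terminology()]).
#' @param sources Named character vector of source file paths; names
#'   are source types (`NDFRT` or `DRUGBANK`).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list per source with `set`, `report` and
#'   the written paths.
#' @export
ddi_run_normalize <- function(concept_file, relation_file, atc_file,
                              sources, out_dir) {
  term <- load_terminology(concept_file, relation_file, atc_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (type in names(sources)) {
    raw <- read_source_file(type, sources[[type]])
    res <- normalize_ddi_list(raw, term)
    set_path <- file.path(out_dir, sprintf("%s_normalized.tsv", tolower(type)))
    rep_path <- file.path(out_dir, sprintf("%s_report.json", tolower(type)))
    write_ddi_set(res$set, set_path)
    write_norm_report(res$report, rep_path)
    out[[type]] <- c(res, list(set_path = set_path, report_path = rep_path))
  }
  invisible(out)
}

#' Compare two normalized sources and the reference set
#'
#' Computes the pairwise overlap report between the two sources and,
#' when reference groups are supplied, the per-group and total coverage
#' of the reference set by each source, writing JSON and aligned-column
#' text tables.
#'
#' @inheritParams ddi_run_normalize
#' @param reference_file Optional reference-group YAML (see
#'   [read_reference_groups()]).
#' @return Invisibly, a list with `overlap`, and `coverage` per source
#'   when a reference file was given.
#' @export
ddi_run_compare <- function(concept_file, relation_file, atc_file,
                            sources, out_dir, reference_file = NULL) {
  term <- load_terminology(concept_file, relation_file, atc_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sets <- lapply(names(sources), function(type)
    normalize_ddi_list(read_source_file(type, sources[[type]]), term)$set)
  names(sets) <- names(sources)
  if (length(sets) < 2L)
    ddi_stop("ddi_contract_error", "compare needs two sources")
  ov <- compare_sets(sets[[1]], sets[[2]])
  jsonlite::write_json(unclass(ov), file.path(out_dir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(utils::capture.output(print(ov)),
             file.path(out_dir, "overlap.txt"))
  out <- list(overlap = ov)
  if (!is.null(reference_file)) {
    groups <- read_reference_groups(reference_file)
    ref <- normalize_ddi_list(build_reference_set(groups), term)$set
    for (nm in names(sets)) {
      cov <- coverage_of_reference(ref, sets[[nm]], groups, term)
      utils::write.table(cov$per_group,
                         file.path(out_dir, sprintf("coverage_%s.tsv", tolower(nm))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[paste0("coverage_", nm)]] <- cov
    }
  }
  invisible(out)
}

#' Abstract sources to ATC class pairs and write class tables
#'
#' Writes the per-class profile table (class, interaction and drug
#' counts per source) and the per-class-pair comparison table
#' (source-specific and shared counts plus the Jaccard score, sorted by
#' total descending).
#'
#' @inheritParams ddi_run_normalize
#' @return Invisibly, a list with `profiles` (per source) and `pairs`
#'   (the class-pair Jaccard table).
#' @export
ddi_run_classmap <- function(concept_file, relation_file, atc_file,
                             sources, out_dir) {
  term <- load_terminology(concept_file, relation_file, atc_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sets <- lapply(names(sources), function(type)
    normalize_ddi_list(read_source_file(type, sources[[type]]), term)$set)
  names(sets) <- names(sources)
  profiles <- lapply(sets, class_profiles, term = term)
  for (nm in names(profiles))
    utils::write.table(profiles[[nm]],
                       file.path(out_dir, sprintf("class_profile_%s.tsv", tolower(nm))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(sets) >= 2L) {
    maps <- lapply(sets[1:2], abstract_to_class_pairs, term = term)
    jac <- class_pair_jaccard(maps[[1]], maps[[2]])
    jac$jaccard <- round(jac$jaccard, 2)
    utils::write.table(jac, file.path(out_dir, "class_pair_jaccard.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else jac <- NULL
  invisible(list(profiles = profiles, pairs = jac))
}

#' Screen prescription lists and write the summary
#'
#' Runs [screen()] over a prescriptions CSV and writes the summary JSON
#' and the top-pairs TSV (pair, frequency, matched-by flag per source).
#'
#' @inheritParams ddi_run_normalize
#' @param prescriptions_file Prescriptions CSV (see
#'   [read_prescriptions()]).
#' @param top_k Number of rows in the top-pairs table.
#' @return Invisibly, a list with `result` and `top`.
#' @export
ddi_run_screen <- function(concept_file, relation_file, atc_file,
                           sources, prescriptions_file, out_dir,
                           top_k = 40L) {
  term <- load_terminology(concept_file, relation_file, atc_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sets <- lapply(names(sources), function(type)
    normalize_ddi_list(read_source_file(type, sources[[type]]), term)$set)
  names(sets) <- names(sources)
  lists <- read_prescriptions(prescriptions_file, term)
  res <- screen(lists, sets, term)
  summary_out <- list(
    total_pairs = res$total_pairs, unique_pairs = res$unique_pairs,
    per_source = res$per_source, both_sources = res$both_sources)
  jsonlite::write_json(summary_out, file.path(out_dir, "screening.json"),
                       auto_unbox = TRUE, digits = NA)
  top <- top_pairs(res, sets, top_k)
  nm <- stats::setNames(term$concepts$name, term$concepts$concept_id)
  top$pair <- sprintf("%s - %s", nm[top$low_id], nm[top$high_id])
  top <- top[c("pair", setdiff(names(top), c("pair", "low_id", "high_id")))]
  utils::write.table(top, file.path(out_dir, "top_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(result = res, top = top))
}

#' Generate a synthetic bundle from the command line surface
#'
#' Thin wrapper over [generator_config()] + [generate_bundle()].
#'
#' @param out_dir Output directory for the bundle.
#' @param seed Integer seed.
#' @param ... Overrides for [generator_config()] fields.
#' @return Invisibly, the `generate_bundle()` result.
#' @export
ddi_run_simulate <- function(out_dir, seed = 1L, ...) {
  cfg <- generator_config(seed = seed, ...)
  invisible(generate_bundle(cfg, out_dir))
}
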