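# Screening of patient prescription lists against normalized DDI sets:
# topical-drug filtering, expansion of clinical-drug lists to unordered
# ingredient pairs (multi-ingredient drugs fan out), and frequency
# accounting of matched pairs.

#' Read prescription lists from CSV
#'
#' Reads the prescription format: columns `patient_id`, `drug_id` (or
#' `drug_name`, resolved via [lookup()]), and optional `count` (repeat
#' count, default 1); one row per prescribed drug, rows grouped into one
#' list per patient.
#'
#' @param path Path to the CSV file.
#' @param term A `ddi_terminology`, required when the file carries
#'   `drug_name` instead of `drug_id`.
#' @return List of prescription lists, each a list with `patient_id`,
#'   `drugs` (character vector of clinical-drug ids) and `count`
#'   (integer repeat count for the whole list, taken from the first
#'   row of the patient's block).
#' @export
read_prescriptions <- function(path, term = NULL) {
  if (!file.exists(path))
    ddi_stop("ddi_parse_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"patient_id" %in% names(df))
    ddi_stop("ddi_parse_error", "%s lacks column patient_id", path)
  if ("drug_id" %in% names(df)) {
    ids <- df$drug_id
  } else if ("drug_name" %in% names(df)) {
    if (is.null(term))
      ddi_stop("ddi_contract_error",
               "terminology required to resolve drug_name column")
    ids <- lookup(term, df$drug_name)
    if (any(is.na(ids)))
      ddi_stop("ddi_resolution_error",
               "unresolvable drug name(s): %s",
               paste(unique(df$drug_name[is.na(ids)]), collapse = ", "))
  } else {
    ddi_stop("ddi_parse_error", "%s lacks drug_id/drug_name column", path)
  }
  cnt <- if ("count" %in% names(df)) {
    x <- suppressWarnings(as.integer(df$count))
    x[is.na(x)] <- 1L
    x
  } else rep(1L, nrow(df))
  pid <- factor(df$patient_id, levels = unique(df$patient_id))
  Map(function(p, d, k) list(patient_id = p, drugs = d, count = k[1]),
      levels(pid), split(ids, pid), split(cnt, pid))
}

#' Drop topical drugs from a prescription list
#'
#' Interaction lists asserted at the ingredient level generally concern
#' systemically administered drugs, so topical products are removed
#' before pairing. Order is preserved.
#'
#' @param list_ A prescription list (`patient_id`, `drugs`, optional
#'   `count`).
#' @param term A `ddi_terminology`; all drug ids must resolve to
#'   clinical drugs.
#' @return The list with `TOPICAL`-route drugs removed.
#' @export
filter_systemic <- function(list_, term) {
  ids <- as.character(list_$drugs)
  i <- match(ids, term$concepts$concept_id)
  if (any(is.na(i)))
    ddi_stop("ddi_resolution_error",
             "patient %s: unknown drug id(s): %s", list_$patient_id,
             paste(unique(ids[is.na(i)]), collapse = ", "))
  tt <- term$concepts$term_type[i]
  if (any(tt != "CLINICAL_DRUG"))
    ddi_stop("ddi_type_error",
             "patient %s: prescription entries must be clinical drugs: %s",
             list_$patient_id,
             paste(unique(ids[tt != "CLINICAL_DRUG"]), collapse = ", "))
  keep <- term$concepts$route_class[i] != "TOPICAL"
  list_$drugs <- ids[keep]
  list_
}

#' Expand a prescription list to canonical ingredient pairs
#'
#' All unordered pairs of distinct clinical drugs in the (already
#' systemic-filtered) list are formed; each drug pair expands to the
#' cross-combination of the two drugs' ingredient sets. Self-pairs
#' (the same ingredient reached from both drugs) are dropped, and a
#' canonical pair occurring several times within one list counts once:
#' one list is one co-prescription event.
#'
#' @param list_ A prescription list.
#' @param term A `ddi_terminology`.
#' @return Character vector of distinct canonical pair keys for this
#'   list (see [canonical_pair()]; key = `low_id`, `high_id` joined by
#'   a separator).
#' @export
expand_to_ingredient_pairs <- function(list_, term) {
  drugs <- unique(as.character(list_$drugs))
  if (length(drugs) < 2L) return(character())
  ings <- lapply(drugs, function(d) ingredients_of(term, d))
  keys <- character()
  for (i in seq_len(length(drugs) - 1L)) {
    for (j in seq(i + 1L, length(drugs))) {
      a <- ings[[i]]
      b <- ings[[j]]
      la <- rep(a, each = length(b))
      lb <- rep(b, times = length(a))
      ok <- la != lb
      if (any(ok))
        keys <- c(keys, pair_key(pmin(la[ok], lb[ok]), pmax(la[ok], lb[ok])))
    }
  }
  unique(keys)
}

#' Screen prescription lists against DDI sources
#'
#' Streams prescription lists through [filter_systemic()] and
#' [expand_to_ingredient_pairs()], accumulating pair frequencies
#' (weighted by each list's repeat count), and matches the pairs
#' against one or more normalized DDI sets. Per-source totals count
#' matched occurrences; uniques count distinct matched pairs. The
#' "both sources" figures use the intersection of the first two
#' sources' pair sets. The result is invariant under reordering of
#' the input lists.
#'
#' @param lists List of prescription lists.
#' @param sources List of `ddi_set` objects (named by their source tag
#'   if the tags are not unique).
#' @param term The shared `ddi_terminology`.
#' @return A `ddi_screening` list: `total_pairs`, `unique_pairs`,
#'   `pair_frequency` (named integer vector keyed by canonical pair),
#'   `per_source` (list of `(total, unique)` per source), and
#'   `both_sources` when two or more sources are given.
#' @export
screen <- function(lists, sources, term) {
  if (!is.list(sources) || length(sources) == 0L)
    ddi_stop("ddi_contract_error", "screen: need at least one ddi_set source")
  if (inherits(sources, "ddi_set")) sources <- list(sources)
  freq <- new.env(parent = emptyenv())
  for (pl in lists) {
    pl <- filter_systemic(pl, term)
    keys <- expand_to_ingredient_pairs(pl, term)
    w <- if (is.null(pl$count)) 1L else as.integer(pl$count)
    for (k in keys) freq[[k]] <- (freq[[k]] %||% 0L) + w
  }
  pf <- unlist(as.list(freq))
  if (is.null(pf)) pf <- stats::setNames(integer(), character())
  pf <- pf[order(names(pf))]

  src_names <- names(sources)
  if (is.null(src_names) || any(!nzchar(src_names)))
    src_names <- vapply(sources, function(s) s$source, character(1))
  names(sources) <- src_names

  match_stats <- function(keys) {
    hit <- names(pf) %in% keys
    list(total = sum(pf[hit]), unique = sum(hit))
  }
  per_source <- lapply(sources, function(s) match_stats(ddi_set_keys(s)))

  out <- list(
    total_pairs = sum(pf),
    unique_pairs = length(pf),
    pair_frequency = pf,
    per_source = per_source
  )
  if (length(sources) >= 2L) {
    both_keys <- Reduce(intersect, lapply(sources[1:2], ddi_set_keys))
    out$both_sources <- match_stats(both_keys)
  }
  class(out) <- "ddi_screening"
  out
}

#' @export
print.ddi_screening <- function(x, ...) {
  cat(sprintf("<ddi_screening> %d pair occurrences, %d unique pairs\n",
              x$total_pairs, x$unique_pairs))
  for (nm in names(x$per_source))
    cat(sprintf("  matched by %-9s total=%d unique=%d\n", nm,
                x$per_source[[nm]]$total, x$per_source[[nm]]$unique))
  if (!is.null(x$both_sources))
    cat(sprintf("  matched by both:    total=%d unique=%d\n",
                x$both_sources$total, x$both_sources$unique))
  invisible(x)
}

#' Most frequent matched pairs
#'
#' The screening analogue of a "top interacting pairs" table: matched
#' pairs sorted by co-prescription frequency descending, ties broken by
#' the canonical pair identifier, flagged with the source(s) whose DDI
#' list contains them.
#'
#' @param result A `ddi_screening` result.
#' @param sources The list of `ddi_set` objects passed to [screen()].
#' @param k Number of rows to return (`k > 0`).
#' @return Data frame: `low_id`, `high_id`, `frequency`, one logical
#'   flag column per source.
#' @export
top_pairs <- function(result, sources, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    ddi_stop("ddi_domain_error", "top_pairs: k must be a positive count")
  src_names <- names(sources)
  if (is.null(src_names) || any(!nzchar(src_names)))
    src_names <- vapply(sources, function(s) s$source, character(1))
  key_sets <- lapply(sources, ddi_set_keys)
  matched <- names(result$pair_frequency)[
    names(result$pair_frequency) %in% unique(unlist(key_sets))]
  if (length(matched) == 0L) {
    df <- split_pair_key(character())
    df$frequency <- integer()
    for (nm in src_names) df[[nm]] <- logical()
    return(df)
  }
  freq <- result$pair_frequency[matched]
  ord <- order(-freq, matched)
  matched <- matched[ord][seq_len(min(k, length(matched)))]
  df <- split_pair_key(matched)
  df$frequency <- as.integer(result$pair_frequency[matched])
  for (i in seq_along(sources)) df[[src_names[i]]] <- matched %in% key_sets[[i]]
  rownames(df) <- NULL
  df
}
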