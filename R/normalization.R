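# Normalization of raw DDI lists to canonical ingredient-level pairs:
# name -> concept mapping, salt collapse, pair canonicalization,
# deduplication, and a conservation-checked audit report.

PAIR_SEP <- "\x1f"

pair_key <- function(low, high) paste(low, high, sep = PAIR_SEP)

split_pair_key <- function(key) {
  parts <- strsplit(key, PAIR_SEP, fixed = TRUE)
  data.frame(low_id = vapply(parts, `[`, character(1), 1L),
             high_id = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Canonicalize an unordered ingredient pair
#'
#' Orders the two ingredient ids lexicographically so that an unordered
#' pair has a unique representation; the distinction between object and
#' precipitant drugs is deliberately not preserved. Vectorized.
#'
#' @param a,b Character vectors of ingredient concept ids.
#' @return Data frame with columns `low_id`, `high_id` where
#'   `low_id < high_id`.
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (any(a == b))
    ddi_stop("ddi_self_pair_error",
             "self-pair: both members are %s; filter self-pairs before canonicalizing",
             paste(unique(a[a == b]), collapse = ", "))
  data.frame(low_id = pmin(a, b), high_id = pmax(a, b),
             stringsAsFactors = FALSE)
}

#' Construct a normalized DDI set
#'
#' Low-level constructor for an ingredient-level DDI set. Most users get
#' these from [normalize_ddi_list()]. Pairs are stored sorted by
#' canonical key, so two sets with equal content are identical objects.
#'
#' @param source One of `NDFRT`, `DRUGBANK`, `REFERENCE`, `OTHER`.
#' @param low_id,high_id Canonical pair members (`low_id < high_id`).
#' @param severity Optional per-pair severity (`SIGNIFICANT`/`CRITICAL`).
#' @param description Optional per-pair free text.
#' @return An object of class `ddi_set`.
#' @export
new_ddi_set <- function(source, low_id, high_id,
                        severity = NA_character_,
                        description = NA_character_) {
  source <- match.arg(source, DDI_SOURCES)
  stopifnot(all(low_id < high_id))
  n <- length(low_id)
  pairs <- data.frame(low_id = as.character(low_id),
                      high_id = as.character(high_id),
                      severity = rep_len(as.character(severity), n),
                      description = rep_len(as.character(description), n),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(pair_key(pairs$low_id, pairs$high_id)))
    ddi_stop("ddi_integrity_error", "duplicate canonical pairs in ddi_set")
  pairs <- pairs[order(pairs$low_id, pairs$high_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(source = source, pairs = pairs), class = "ddi_set")
}

#' @export
print.ddi_set <- function(x, ...) {
  cat(sprintf("<ddi_set> source=%s, %d canonical ingredient pairs\n",
              x$source, nrow(x$pairs)))
  if (x$source == "NDFRT") {
    sev <- table(x$pairs$severity)
    cat("  severity:", paste(sprintf("%s=%d", names(sev), sev), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
length.ddi_set <- function(x) nrow(x$pairs)

ddi_set_keys <- function(s) pair_key(s$pairs$low_id, s$pairs$high_id)

#' Normalize a raw DDI list against a terminology
#'
#' The core normalization step. Each drug name is looked up in the
#' terminology (exact match first, then normalized match); records with
#' an unmappable name are discarded and counted. Hits on
#' precise-ingredient (salt/ester) concepts collapse to their base
#' ingredient, which can make previously distinct records redundant;
#' those collapse into one canonical pair. Names resolving to clinical
#' drugs are dropped (the ingredient-level lists under comparison do not
#' carry products), as are pairs whose two members collapse to the same
#' ingredient. When duplicates carry different severities the maximum
#' severity is kept (`CRITICAL` > `SIGNIFICANT`); descriptions merge to
#' the lexicographically smallest so the result is independent of input
#' order.
#'
#' @param raw A `ddi_raw` data frame; all rows must share one source tag.
#' @param term A `ddi_terminology`.
#' @return A list with components `set` (a [new_ddi_set()] object) and
#'   `report` (a `ddi_norm_report`: counters `total_input`,
#'   `unmapped_ddis`, `unmapped_drugs`, `collapsed_duplicates`,
#'   `self_pairs_dropped`, `multi_ingredient_dropped`, `output_size`,
#'   satisfying `output_size = total_input - unmapped_ddis -
#'   collapsed_duplicates - self_pairs_dropped - multi_ingredient_dropped`).
#' @export
normalize_ddi_list <- function(raw, term) {
  src <- unique(as.character(raw$source))
  if (length(src) > 1L)
    ddi_stop("ddi_contract_error",
             "normalize_ddi_list requires a single source tag; got: %s",
             paste(src, collapse = ", "))
  if (length(src) == 0L) src <- "OTHER"

  n <- nrow(raw)
  report <- list(total_input = n, unmapped_ddis = 0L, unmapped_drugs = 0L,
                 collapsed_duplicates = 0L, self_pairs_dropped = 0L,
                 multi_ingredient_dropped = 0L, output_size = 0L)

  if (n == 0L) {
    out <- new_ddi_set(src, character(), character())
    class(report) <- "ddi_norm_report"
    return(list(set = out, report = report))
  }

  cid_a <- lookup(term, raw$drug_a_name)
  cid_b <- lookup(term, raw$drug_b_name)

  unmapped <- is.na(cid_a) | is.na(cid_b)
  bad_names <- unique(normalize_name(
    c(raw$drug_a_name[is.na(cid_a)], raw$drug_b_name[is.na(cid_b)])))
  report$unmapped_ddis <- sum(unmapped)
  report$unmapped_drugs <- length(bad_names)

  keep <- !unmapped
  tt_a <- term_type_of(term, cid_a)
  tt_b <- term_type_of(term, cid_b)
  is_drug <- keep & (tt_a == "CLINICAL_DRUG" | tt_b == "CLINICAL_DRUG")
  report$multi_ingredient_dropped <- sum(is_drug, na.rm = TRUE)
  keep <- keep & !is_drug

  ing_a <- rep(NA_character_, n)
  ing_b <- rep(NA_character_, n)
  ing_a[keep] <- to_ingredient(term, cid_a[keep])
  ing_b[keep] <- to_ingredient(term, cid_b[keep])

  selfp <- keep & ing_a == ing_b
  report$self_pairs_dropped <- sum(selfp)
  keep <- keep & !selfp

  if (!any(keep)) {
    out <- new_ddi_set(src, character(), character())
    report$output_size <- 0L
    class(report) <- "ddi_norm_report"
    return(list(set = out, report = report))
  }

  cp <- canonical_pair(ing_a[keep], ing_b[keep])
  key <- pair_key(cp$low_id, cp$high_id)
  sev <- raw$severity[keep]
  des <- raw$description[keep]

  report$collapsed_duplicates <- sum(duplicated(key))

  merge_sev <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_character_)
    if (any(v == "CRITICAL")) "CRITICAL" else "SIGNIFICANT"
  }
  merge_des <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_character_ else min(v)
  }
  fkey <- factor(key, levels = unique(key))
  sev_m <- tapply(sev, fkey, merge_sev)
  des_m <- tapply(des, fkey, merge_des)
  first <- !duplicated(key)

  out <- new_ddi_set(src, cp$low_id[first], cp$high_id[first],
                     severity = unname(sev_m[key[first]]),
                     description = unname(des_m[key[first]]))
  report$output_size <- nrow(out$pairs)
  stopifnot(report$output_size ==
              report$total_input - report$unmapped_ddis -
              report$collapsed_duplicates - report$self_pairs_dropped -
              report$multi_ingredient_dropped)
  class(report) <- "ddi_norm_report"
  list(set = out, report = report)
}

#' @export
print.ddi_norm_report <- function(x, ...) {
  cat("<ddi_norm_report>\n")
  for (f in names(unclass(x))) cat(sprintf("  %-24s %d\n", f, x[[f]]))
  invisible(x)
}

#' Serialize and re-read normalized DDI sets
#'
#' TSV round-trip for a normalized set (columns `low_id`, `high_id`,
#' `severity`, `description`); the audit report is written as JSON.
#'
#' @param set A `ddi_set`.
#' @param path Output path.
#' @param source Source tag to attach when reading back.
#' @param report A `ddi_norm_report`.
#' @return `path` invisibly for the writers; the reconstructed object
#'   for the readers.
#' @export
write_ddi_set <- function(set, path) {
  utils::write.table(set$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ddi_set
#' @export
read_ddi_set <- function(path, source = "OTHER") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  df$severity[!nzchar(df$severity)] <- NA_character_
  df$description[!nzchar(df$description)] <- NA_character_
  new_ddi_set(source, df$low_id, df$high_id, df$severity, df$description)
}

#' @rdname write_ddi_set
#' @export
write_norm_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Re-express a normalized set as raw records
#'
#' Maps a normalized set's ingredient ids back to their preferred names,
#' yielding a raw DDI table that, when normalized again, reproduces the
#' set with an all-zero discard report. Useful for idempotence checks
#' and for exporting a set in the raw record format.
#'
#' @param set A `ddi_set`.
#' @param term The `ddi_terminology` the set was normalized against.
#' @return A `ddi_raw` data frame.
#' @export
ddi_set_to_raw <- function(set, term) {
  nm <- stats::setNames(term$concepts$name, term$concepts$concept_id)
  raw_ddi_frame(set$source, unname(nm[set$pairs$low_id]),
                unname(nm[set$pairs$high_id]),
                severity = set$pairs$severity,
                description = set$pairs$description)
}
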