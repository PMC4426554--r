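# Overlap between two normalized DDI sets, coverage of the reference
# set (overall and per group), and severity-stratified coverage.

#' Integer percentage, rounded half-up
#'
#' `100 * numerator / denominator` rounded half-up to the nearest
#' integer, computed in exact integer arithmetic. This is the rounding
#' convention used for every percentage the package reports.
#'
#' @param numerator,denominator Non-negative counts,
#'   `numerator <= denominator`, `denominator > 0`.
#' @return Integer percent in `0:100`. Vectorized over `numerator`.
#' @examples
#' round_percent(207, 360)  # 58
#' round_percent(146, 207)  # 71
#' @export
round_percent <- function(numerator, denominator) {
  if (any(denominator <= 0))
    ddi_stop("ddi_domain_error", "round_percent: denominator must be > 0")
  if (any(numerator < 0 | numerator > denominator))
    ddi_stop("ddi_domain_error",
             "round_percent: need 0 <= numerator <= denominator")
  as.integer((200 * numerator + denominator) %/% (2 * denominator))
}

#' Compare two normalized DDI sets
#'
#' Exact set algebra on canonical ingredient pairs: shared and
#' source-specific counts, plus the mutual coverage percentages
#' (`coverage_a_by_b_pct` is the percentage of `a`'s pairs also found
#' in `b`).
#'
#' @param a,b `ddi_set` objects normalized against the same terminology.
#' @return A `ddi_overlap` list: `source_a`, `source_b`, `size_a`,
#'   `size_b`, `shared`, `only_a`, `only_b`, `coverage_a_by_b_pct`,
#'   `coverage_b_by_a_pct`.
#' @export
compare_sets <- function(a, b) {
  ka <- ddi_set_keys(a)
  kb <- ddi_set_keys(b)
  shared <- length(intersect(ka, kb))
  out <- list(
    source_a = a$source, source_b = b$source,
    size_a = length(ka), size_b = length(kb),
    shared = shared,
    only_a = length(ka) - shared,
    only_b = length(kb) - shared,
    coverage_a_by_b_pct = if (length(ka) > 0) round_percent(shared, length(ka)) else NA_integer_,
    coverage_b_by_a_pct = if (length(kb) > 0) round_percent(shared, length(kb)) else NA_integer_
  )
  class(out) <- "ddi_overlap"
  out
}

#' @export
print.ddi_overlap <- function(x, ...) {
  cat(sprintf("<ddi_overlap> %s (n=%d) vs %s (n=%d)\n",
              x$source_a, x$size_a, x$source_b, x$size_b))
  cat(sprintf("  shared %d | only %s %d | only %s %d\n",
              x$shared, x$source_a, x$only_a, x$source_b, x$only_b))
  cat(sprintf("  coverage of %s by %s: %s%%; of %s by %s: %s%%\n",
              x$source_a, x$source_b, x$coverage_a_by_b_pct,
              x$source_b, x$source_a, x$coverage_b_by_a_pct))
  invisible(x)
}

#' Reference-set coverage, overall and per group
#'
#' Measures how many of the reference pairs a source covers, broken
#' down by reference group. Each group's pairs are rebuilt from its
#' member lists and normalized against the terminology; a pair
#' belonging to two groups counts in each group's row but once in the
#' total.
#'
#' @param ref `ddi_set` built by normalizing [build_reference_set()]
#'   output.
#' @param source `ddi_set` for the source under evaluation.
#' @param groups Reference group definitions (see
#'   [read_reference_groups()]).
#' @param term The shared `ddi_terminology`.
#' @return A `ddi_group_coverage` list with `per_group` (data frame:
#'   `group_id`, `label`, `n_pairs`, `matched`, `matched_pct`) and
#'   `total` (`n_pairs`, `matched`, `matched_pct` on deduplicated
#'   pairs).
#' @export
coverage_of_reference <- function(ref, source, groups, term) {
  src_keys <- ddi_set_keys(source)
  group_keys <- lapply(groups, function(g) {
    raw <- build_reference_set(list(g))
    ddi_set_keys(normalize_ddi_list(raw, term)$set)
  })
  per_group <- data.frame(
    group_id = vapply(groups, function(g) as.integer(g$group_id), integer(1)),
    label = vapply(groups, function(g) as.character(g$label %||% ""), character(1)),
    n_pairs = vapply(group_keys, length, integer(1)),
    matched = vapply(group_keys, function(k) length(intersect(k, src_keys)),
                     integer(1)),
    stringsAsFactors = FALSE
  )
  per_group$matched_pct <- ifelse(
    per_group$n_pairs > 0,
    mapply(round_percent, per_group$matched, pmax(per_group$n_pairs, 1L)),
    NA_integer_)
  ref_keys <- ddi_set_keys(ref)
  total <- list(n_pairs = length(ref_keys),
                matched = length(intersect(ref_keys, src_keys)))
  total$matched_pct <- if (total$n_pairs > 0)
    round_percent(total$matched, total$n_pairs) else NA_integer_
  structure(list(source = source$source, per_group = per_group, total = total),
            class = "ddi_group_coverage")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.ddi_group_coverage <- function(x, ...) {
  cat(sprintf("<ddi_group_coverage> source=%s\n", x$source))
  df <- x$per_group
  df$coverage <- sprintf("%d (%d%%)", df$matched, df$matched_pct)
  print(df[, c("group_id", "label", "n_pairs", "coverage")], row.names = FALSE)
  cat(sprintf("  TOTAL %d / %d (%d%%)\n", x$total$matched, x$total$n_pairs,
              x$total$matched_pct))
  invisible(x)
}

#' Severity-stratified coverage of one set by another
#'
#' For each severity stratum of `a` (a set whose every pair carries a
#' severity annotation), the percentage of that stratum's pairs also
#' present in `b`. Empty strata are omitted.
#'
#' @param a `ddi_set` with a severity for every pair.
#' @param b `ddi_set` to test coverage against.
#' @return Named integer vector, one percentage per severity stratum
#'   present in `a`.
#' @export
severity_stratified_coverage <- function(a, b) {
  if (any(is.na(a$pairs$severity)))
    ddi_stop("ddi_contract_error",
             "severity_stratified_coverage: set %s has pairs without severity",
             a$source)
  kb <- ddi_set_keys(b)
  ka <- ddi_set_keys(a)
  out <- integer()
  for (s in SEVERITIES) {
    stratum <- ka[a$pairs$severity == s]
    if (length(stratum) == 0L) next
    out[[s]] <- round_percent(length(intersect(stratum, kb)), length(stratum))
  }
  out
}
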