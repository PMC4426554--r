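# Abstraction of ingredient-level DDI sets to 4th-level ATC class
# pairs: per-class profiles and per-class-pair Jaccard similarity
# between two sources.

CLASS_SEP <- "\x1e"

class_pair_key <- function(ca, cb) {
  paste(pmin(ca, cb), pmax(ca, cb), sep = CLASS_SEP)
}

split_class_key <- function(key) {
  parts <- strsplit(key, CLASS_SEP, fixed = TRUE)
  data.frame(class_a = vapply(parts, `[`, character(1), 1L),
             class_b = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Abstract a DDI set to ATC class pairs
#'
#' Maps each canonical ingredient pair to the unordered pair(s) of
#' 4th-level ATC classes its members belong to. A DDI with an
#' ATC-less member is excluded (and counted in the `excluded`
#' attribute); a DDI whose members carry multiple classes fans out to
#' every class-pair combination. Both members in one class yields the
#' same-class pair `(c, c)`.
#'
#' @param s A `ddi_set`.
#' @param term The `ddi_terminology` the set was normalized against.
#' @return Named list: class-pair key -> character vector of canonical
#'   pair keys, with attributes `excluded` (number of DDIs dropped for
#'   missing ATC coverage) and `n_abstracted`.
#' @export
abstract_to_class_pairs <- function(s, term) {
  keys <- ddi_set_keys(s)
  out <- new.env(parent = emptyenv())
  excluded <- 0L
  for (i in seq_along(keys)) {
    ca <- atc_classes(term, s$pairs$low_id[i])
    cb <- atc_classes(term, s$pairs$high_id[i])
    if (length(ca) == 0L || length(cb) == 0L) {
      excluded <- excluded + 1L
      next
    }
    combos <- unique(class_pair_key(rep(ca, each = length(cb)),
                                    rep(cb, times = length(ca))))
    for (k in combos) out[[k]] <- c(out[[k]], keys[i])
  }
  res <- as.list(out)
  if (length(res) > 0L) res <- res[order(names(res))]
  attr(res, "excluded") <- excluded
  attr(res, "n_abstracted") <- length(keys) - excluded
  res
}

#' Per-class DDI and drug counts
#'
#' For every 4th-level ATC class touched by a DDI set: the number of
#' distinct DDIs with at least one member in the class, and the number
#' of distinct member ingredients of the class occurring in those DDIs.
#'
#' @param s A `ddi_set`.
#' @param term The shared `ddi_terminology`.
#' @return Data frame with columns `atc_code`, `atc_name`, `ddi_count`,
#'   `drug_count`, sorted by `ddi_count` descending.
#' @export
class_profiles <- function(s, term) {
  keys <- ddi_set_keys(s)
  ddis <- new.env(parent = emptyenv())
  drugs <- new.env(parent = emptyenv())
  note <- function(cls, ing, key) {
    for (cl in cls) {
      ddis[[cl]] <- c(ddis[[cl]], key)
      drugs[[cl]] <- c(drugs[[cl]], ing)
    }
  }
  for (i in seq_along(keys)) {
    note(atc_classes(term, s$pairs$low_id[i]), s$pairs$low_id[i], keys[i])
    note(atc_classes(term, s$pairs$high_id[i]), s$pairs$high_id[i], keys[i])
  }
  codes <- sort(names(as.list(ddis)))
  if (length(codes) == 0L)
    return(data.frame(atc_code = character(), atc_name = character(),
                      ddi_count = integer(), drug_count = integer(),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    atc_code = codes,
    atc_name = unname(ifelse(is.na(term$atc_names[codes]), "",
                             term$atc_names[codes])),
    ddi_count = vapply(codes, function(cl) length(unique(ddis[[cl]])), integer(1)),
    drug_count = vapply(codes, function(cl) length(unique(drugs[[cl]])), integer(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$ddi_count, df$atc_code), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Jaccard similarity per ATC class pair
#'
#' Compares two class-pair abstractions (see
#' [abstract_to_class_pairs()]): for every class pair present in either
#' map, the counts of source-specific and shared DDIs and the Jaccard
#' score `shared / (shared + only_a + only_b)`.
#'
#' @param a_map,b_map Class-pair maps produced against the same
#'   terminology.
#' @return Data frame with columns `class_a`, `class_b`, `total`,
#'   `only_a`, `only_b`, `shared`, `jaccard`, sorted by `total`
#'   descending (ties by class pair). Jaccard is reported at full
#'   precision; round for display.
#' @export
class_pair_jaccard <- function(a_map, b_map) {
  all_keys <- sort(union(names(a_map), names(b_map)))
  if (length(all_keys) == 0L)
    return(data.frame(class_a = character(), class_b = character(),
                      total = integer(), only_a = integer(),
                      only_b = integer(), shared = integer(),
                      jaccard = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(all_keys, function(k) {
    pa <- unique(a_map[[k]])
    pb <- unique(b_map[[k]])
    shared <- length(intersect(pa, pb))
    data.frame(key = k,
               only_a = length(pa) - shared,
               only_b = length(pb) - shared,
               shared = shared, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  cls <- split_class_key(df$key)
  df <- cbind(cls, df[c("only_a", "only_b", "shared")])
  df$total <- df$only_a + df$only_b + df$shared
  df$jaccard <- ifelse(df$total > 0, df$shared / df$total, NA_real_)
  df <- df[order(-df$total, df$class_a, df$class_b),
           c("class_a", "class_b", "total", "only_a", "only_b", "shared",
             "jaccard")]
  rownames(df) <- NULL
  df
}
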