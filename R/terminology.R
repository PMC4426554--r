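# In-memory model of an ingredient-level drug terminology: concept store,
# name index, salt -> base and clinical-drug -> ingredient links, ATC
# class assignments at the 4th (chemical/therapeutic subgroup) level.

TERM_TYPES <- c("INGREDIENT", "PRECISE_INGREDIENT", "CLINICAL_DRUG")
ROUTE_CLASSES <- c("SYSTEMIC", "TOPICAL", "NOT_APPLICABLE")

ddi_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "ddi_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Normalize a drug name string
#'
#' Deterministic local normalization used for name matching: case-fold,
#' strip leading/trailing whitespace, collapse internal whitespace runs to
#' a single space, and delete the punctuation characters `,.;:'"()/-`.
#' Idempotent; an empty input yields an empty string.
#'
#' @param raw Character vector of raw drug names.
#' @return Character vector of normalized names, same length as `raw`.
#' @examples
#' normalize_name("St. John's wort")   # "st johns wort"
#' normalize_name("  Diltiazem   Hydrocloride ")
#' @export
normalize_name <- function(raw) {
  x <- tolower(as.character(raw))
  x <- gsub("[,.;:'\"()/-]", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Construct a terminology from in-memory tables
#'
#' Builds and validates the terminology object used throughout the
#' pipeline. Most users will call [load_terminology()] on TSV files
#' instead; the synthetic-data generator and tests build tables directly.
#'
#' @param concepts Data frame with columns `concept_id`, `name`,
#'   `term_type` (one of `INGREDIENT`, `PRECISE_INGREDIENT`,
#'   `CLINICAL_DRUG`), `route_class` (`SYSTEMIC`, `TOPICAL`,
#'   `NOT_APPLICABLE`), `obsolete` (0/1 or logical).
#' @param relations Data frame with columns `rel_type`
#'   (`has_ingredient_base` for salt -> base ingredient,
#'   `has_ingredient` for clinical drug -> ingredient), `source_id`,
#'   `target_id`. May have zero rows.
#' @param atc Data frame with columns `ingredient_id`, `atc_code`,
#'   `atc_name`. May have zero rows.
#' @return An object of class `ddi_terminology`.
#' @export
new_terminology <- function(concepts,
                            relations = data.frame(rel_type = character(),
                                                   source_id = character(),
                                                   target_id = character()),
                            atc = data.frame(ingredient_id = character(),
                                             atc_code = character(),
                                             atc_name = character())) {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  atc <- as.data.frame(atc, stringsAsFactors = FALSE)

  need <- c("concept_id", "name", "term_type", "route_class", "obsolete")
  missing_cols <- setdiff(need, names(concepts))
  if (length(missing_cols) > 0L)
    ddi_stop("ddi_parse_error", "concept table lacks column(s): %s",
             paste(missing_cols, collapse = ", "))
  concepts$concept_id <- as.character(concepts$concept_id)
  concepts$name <- as.character(concepts$name)
  concepts$obsolete <- as.logical(as.integer(concepts$obsolete))

  if (any(!nzchar(concepts$concept_id)))
    ddi_stop("ddi_integrity_error", "empty concept_id in concept table")
  dup <- concepts$concept_id[duplicated(concepts$concept_id)]
  if (length(dup) > 0L)
    ddi_stop("ddi_integrity_error", "duplicate concept_id(s): %s",
             paste(unique(dup), collapse = ", "))
  bad_tt <- setdiff(unique(concepts$term_type), TERM_TYPES)
  if (length(bad_tt) > 0L)
    ddi_stop("ddi_parse_error", "unknown term_type(s): %s",
             paste(bad_tt, collapse = ", "))
  bad_rc <- setdiff(unique(concepts$route_class), ROUTE_CLASSES)
  if (length(bad_rc) > 0L)
    ddi_stop("ddi_parse_error", "unknown route_class(es): %s",
             paste(bad_rc, collapse = ", "))
  off_route <- concepts$term_type != "CLINICAL_DRUG" &
    concepts$route_class != "NOT_APPLICABLE"
  if (any(off_route))
    ddi_stop("ddi_integrity_error",
             "route_class must be NOT_APPLICABLE for non-clinical-drug concept(s): %s",
             paste(concepts$concept_id[off_route], collapse = ", "))

  norm <- normalize_name(concepts$name)
  coll <- norm[duplicated(norm)]
  if (length(coll) > 0L)
    ddi_stop("ddi_integrity_error",
             "concept names collide after normalization: %s",
             paste(unique(coll), collapse = ", "))

  term_type_of <- stats::setNames(concepts$term_type, concepts$concept_id)

  pr <- relations[relations$rel_type == "has_ingredient_base", , drop = FALSE]
  dr <- relations[relations$rel_type == "has_ingredient", , drop = FALSE]
  bad_rel <- setdiff(unique(relations$rel_type),
                     c("has_ingredient_base", "has_ingredient"))
  if (length(bad_rel) > 0L)
    ddi_stop("ddi_parse_error", "unknown rel_type(s): %s",
             paste(bad_rel, collapse = ", "))

  check_ids <- function(ids, want, what) {
    tt <- term_type_of[ids]
    bad <- ids[is.na(tt) | tt != want]
    if (length(bad) > 0L)
      ddi_stop("ddi_integrity_error",
               "%s must reference %s concepts; offending id(s): %s",
               what, want, paste(unique(bad), collapse = ", "))
  }
  check_ids(pr$source_id, "PRECISE_INGREDIENT", "has_ingredient_base source")
  check_ids(pr$target_id, "INGREDIENT", "has_ingredient_base target")
  check_ids(dr$source_id, "CLINICAL_DRUG", "has_ingredient source")
  check_ids(dr$target_id, "INGREDIENT", "has_ingredient target")
  if (anyDuplicated(pr$source_id))
    ddi_stop("ddi_integrity_error",
             "precise ingredient(s) with more than one base: %s",
             paste(unique(pr$source_id[duplicated(pr$source_id)]), collapse = ", "))

  precise_ids <- concepts$concept_id[concepts$term_type == "PRECISE_INGREDIENT"]
  orphan_salts <- setdiff(precise_ids, pr$source_id)
  if (length(orphan_salts) > 0L)
    ddi_stop("ddi_integrity_error",
             "precise ingredient(s) without a base-ingredient link: %s",
             paste(orphan_salts, collapse = ", "))
  drug_ids <- concepts$concept_id[concepts$term_type == "CLINICAL_DRUG"]
  orphan_drugs <- setdiff(drug_ids, dr$source_id)
  if (length(orphan_drugs) > 0L)
    ddi_stop("ddi_integrity_error",
             "clinical drug(s) without ingredient links: %s",
             paste(orphan_drugs, collapse = ", "))

  if (nrow(atc) > 0L) {
    need_atc <- c("ingredient_id", "atc_code")
    if (!all(need_atc %in% names(atc)))
      ddi_stop("ddi_parse_error", "atc table lacks column(s): %s",
               paste(setdiff(need_atc, names(atc)), collapse = ", "))
    check_ids(as.character(atc$ingredient_id), "INGREDIENT", "atc assignment")
  }

  structure(list(
    concepts = concepts,
    name_exact = stats::setNames(concepts$concept_id, concepts$name),
    name_index = stats::setNames(concepts$concept_id, norm),
    precise_to_ingredient = stats::setNames(as.character(pr$target_id),
                                            as.character(pr$source_id)),
    drug_to_ingredients = lapply(
      split(as.character(dr$target_id), factor(dr$source_id, levels = unique(dr$source_id))),
      unique),
    atc = lapply(
      split(as.character(atc$atc_code),
            factor(atc$ingredient_id, levels = unique(atc$ingredient_id))),
      unique),
    atc_names = if (nrow(atc) > 0L && "atc_name" %in% names(atc))
      stats::setNames(as.character(atc$atc_name), as.character(atc$atc_code))[
        !duplicated(as.character(atc$atc_code))]
    else stats::setNames(character(), character())
  ), class = "ddi_terminology")
}

#' Load a terminology from TSV files
#'
#' Reads the three-file terminology bundle: a concept table, a relation
#' table (salt -> base ingredient, clinical drug -> ingredient), and an
#' ATC assignment table. All files are tab-separated UTF-8 with a header
#' row. Duplicate normalized names or dangling link identifiers abort the
#' load with an integrity error.
#'
#' @param concept_file Path to `concepts.tsv` (columns `concept_id`,
#'   `name`, `term_type`, `route_class`, `obsolete`).
#' @param relation_file Path to `relations.tsv` (columns `rel_type`,
#'   `source_id`, `target_id`).
#' @param atc_file Path to `atc.tsv` (columns `ingredient_id`, `atc_code`,
#'   `atc_name`).
#' @return A `ddi_terminology` object.
#' @seealso [new_terminology()] for in-memory construction.
#' @export
load_terminology <- function(concept_file, relation_file, atc_file) {
  read_tsv_checked <- function(path, cols) {
    if (!file.exists(path))
      ddi_stop("ddi_parse_error", "file not found: %s", path)
    df <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE,
                        colClasses = "character", quote = ""),
      error = function(e)
        ddi_stop("ddi_parse_error", "cannot parse %s: %s", path, conditionMessage(e)))
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols) > 0L)
      ddi_stop("ddi_parse_error", "%s lacks column(s): %s", path,
               paste(missing_cols, collapse = ", "))
    df
  }
  concepts <- read_tsv_checked(concept_file,
                               c("concept_id", "name", "term_type",
                                 "route_class", "obsolete"))
  relations <- read_tsv_checked(relation_file,
                                c("rel_type", "source_id", "target_id"))
  atc <- read_tsv_checked(atc_file, c("ingredient_id", "atc_code", "atc_name"))
  new_terminology(concepts, relations, atc)
}

#' @export
print.ddi_terminology <- function(x, ...) {
  tt <- table(factor(x$concepts$term_type, levels = TERM_TYPES))
  cat("<ddi_terminology>\n")
  cat(sprintf("  %d concepts: %d ingredients, %d precise ingredients, %d clinical drugs\n",
              nrow(x$concepts), tt[["INGREDIENT"]], tt[["PRECISE_INGREDIENT"]],
              tt[["CLINICAL_DRUG"]]))
  cat(sprintf("  %d salt->base links, %d drug->ingredient maps, %d ingredients with ATC classes\n",
              length(x$precise_to_ingredient), length(x$drug_to_ingredients),
              length(x$atc)))
  invisible(x)
}

term_type_of <- function(term, cid) {
  i <- match(cid, term$concepts$concept_id)
  ifelse(is.na(i), NA_character_, term$concepts$term_type[i])
}

#' Look up a drug name in a terminology
#'
#' Tries an exact match on the stored preferred name first, then a
#' normalized match (see [normalize_name()]). Obsolete concepts are never
#' returned: a hit on an obsolete concept counts as absence.
#'
#' @param term A `ddi_terminology`.
#' @param name Character vector of drug names.
#' @return Character vector of concept ids, `NA` where no (non-obsolete)
#'   concept matches. Absence is a value, not an error.
#' @export
lookup <- function(term, name) {
  hit <- unname(term$name_exact[as.character(name)])
  miss <- is.na(hit)
  if (any(miss))
    hit[miss] <- unname(term$name_index[normalize_name(name[miss])])
  obs <- stats::setNames(term$concepts$obsolete, term$concepts$concept_id)
  hit[!is.na(hit) & obs[hit]] <- NA_character_
  hit
}

#' Collapse a salt form to its base ingredient
#'
#' Ingredient ids map to themselves; precise-ingredient (salt/ester) ids
#' map through the salt -> base link. The result always has term type
#' `INGREDIENT`.
#'
#' @param term A `ddi_terminology`.
#' @param cid Character vector of ingredient or precise-ingredient ids.
#' @return Character vector of ingredient ids.
#' @export
to_ingredient <- function(term, cid) {
  cid <- as.character(cid)
  tt <- term_type_of(term, cid)
  bad <- is.na(tt) | !(tt %in% c("INGREDIENT", "PRECISE_INGREDIENT"))
  if (any(bad))
    ddi_stop("ddi_type_error",
             "to_ingredient requires ingredient or precise-ingredient ids; got: %s",
             paste(unique(cid[bad]), collapse = ", "))
  out <- cid
  sel <- tt == "PRECISE_INGREDIENT"
  out[sel] <- unname(term$precise_to_ingredient[cid[sel]])
  out
}

#' Ingredients of a clinical drug
#'
#' @param term A `ddi_terminology`.
#' @param cid A single clinical-drug concept id.
#' @return Character vector of ingredient ids (length >= 1). A drug with
#'   two or more ingredients is a multi-ingredient drug.
#' @export
ingredients_of <- function(term, cid) {
  cid <- as.character(cid)
  stopifnot(length(cid) == 1L)
  tt <- term_type_of(term, cid)
  if (is.na(tt) || tt != "CLINICAL_DRUG")
    ddi_stop("ddi_type_error",
             "ingredients_of requires a clinical-drug id; got %s (%s)",
             cid, ifelse(is.na(tt), "unknown", tt))
  term$drug_to_ingredients[[cid]]
}

#' ATC classes of an ingredient
#'
#' Returns the 4th-level ATC class codes assigned to an ingredient. An
#' empty result means the ingredient is outside the ATC classification.
#'
#' @param term A `ddi_terminology`.
#' @param ingredient_id A single ingredient concept id.
#' @return Character vector of ATC class codes (possibly empty).
#' @export
atc_classes <- function(term, ingredient_id) {
  ingredient_id <- as.character(ingredient_id)
  stopifnot(length(ingredient_id) == 1L)
  tt <- term_type_of(term, ingredient_id)
  if (is.na(tt) || tt != "INGREDIENT")
    ddi_stop("ddi_type_error",
             "atc_classes requires an ingredient id; got %s (%s)",
             ingredient_id, ifelse(is.na(tt), "unknown", tt))
  cls <- term$atc[[ingredient_id]]
  if (is.null(cls)) character() else cls
}
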