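# Readers for raw DDI lists: the DrugBank-style XML dialect, the
# NDF-RT-style severity-annotated record format, and curated reference
# groups (object members x precipitant members).

DDI_SOURCES <- c("NDFRT", "DRUGBANK", "REFERENCE", "OTHER")
SEVERITIES <- c("SIGNIFICANT", "CRITICAL")

raw_ddi_frame <- function(source, drug_a_name, drug_b_name,
                          severity = NA_character_,
                          description = NA_character_) {
  n <- length(drug_a_name)
  structure(data.frame(
    source = rep_len(as.character(source), n),
    drug_a_name = as.character(drug_a_name),
    drug_b_name = as.character(drug_b_name),
    severity = rep_len(as.character(severity), n),
    description = rep_len(as.character(description), n),
    stringsAsFactors = FALSE
  ), class = c("ddi_raw", "data.frame"))
}

#' Read interactions from a DrugBank-style XML file
#'
#' Parses the XML dialect
#' `<drugbank><drug><name/>...<drug-interactions><drug-interaction>` and
#' emits one raw DDI row per `<drug-interaction>` element: the enclosing
#' drug record's name on one side, the interaction partner's name on the
#' other, with the free-text description captured. Severity is never
#' present in this format. All other elements are ignored.
#'
#' @param path Path to the XML file.
#' @return A `ddi_raw` data frame with columns `source` (`"DRUGBANK"`),
#'   `drug_a_name`, `drug_b_name`, `severity` (all `NA`), `description`.
#' @export
read_drugbank_xml <- function(path) {
  if (!file.exists(path))
    ddi_stop("ddi_parse_error", "file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    ddi_stop("ddi_parse_error", "malformed XML in %s: %s",
                             path, conditionMessage(e)))
  drugs <- xml2::xml_find_all(doc, "/drugbank/drug")
  rows <- lapply(drugs, function(drug) {
    a <- xml2::xml_text(xml2::xml_find_first(drug, "./name"))
    ints <- xml2::xml_find_all(drug, "./drug-interactions/drug-interaction")
    if (length(ints) == 0L) return(NULL)
    data.frame(
      drug_a_name = a,
      drug_b_name = vapply(ints, function(i)
        xml2::xml_text(xml2::xml_find_first(i, "./name")), character(1)),
      description = vapply(ints, function(i)
        xml2::xml_text(xml2::xml_find_first(i, "./description")), character(1)),
      stringsAsFactors = FALSE
    )
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(raw_ddi_frame(character(), character(), character()))
  raw_ddi_frame("DRUGBANK", rows$drug_a_name, rows$drug_b_name,
                description = rows$description)
}

#' Read interactions from an NDF-RT-style record file
#'
#' Reads the tab-separated record format `drug_a`, `drug_b`, `severity`
#' (header required). Severity must be `significant` or `critical`
#' (case-insensitive); any other token is a value error.
#'
#' @param path Path to the TSV file.
#' @return A `ddi_raw` data frame with `source = "NDFRT"` and severity
#'   upper-cased to `SIGNIFICANT` / `CRITICAL`.
#' @export
read_ndfrt_records <- function(path) {
  if (!file.exists(path))
    ddi_stop("ddi_parse_error", "file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character", quote = ""),
    error = function(e)
      ddi_stop("ddi_parse_error", "cannot parse %s: %s", path,
               conditionMessage(e)))
  need <- c("drug_a", "drug_b", "severity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    ddi_stop("ddi_parse_error", "%s lacks column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  sev <- toupper(df$severity)
  bad <- !(sev %in% SEVERITIES)
  if (any(bad))
    ddi_stop("ddi_value_error",
             "%s: severity must be significant or critical; offending value(s): %s",
             path, paste(unique(df$severity[bad]), collapse = ", "))
  raw_ddi_frame("NDFRT", df$drug_a, df$drug_b, severity = sev)
}

#' Read reference-group definitions from YAML
#'
#' Each group defines a block of reference interactions as the
#' cross-product of its object members and precipitant members.
#'
#' @param path Path to a YAML file: a list of `{group_id, label,
#'   objects: [...], precipitants: [...]}` entries.
#' @return A list of reference groups, each a list with fields
#'   `group_id`, `label`, `objects`, `precipitants`.
#' @export
read_reference_groups <- function(path) {
  if (!file.exists(path))
    ddi_stop("ddi_parse_error", "file not found: %s", path)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(g) {
    g$objects <- as.character(g$objects)
    g$precipitants <- as.character(g$precipitants)
    validate_reference_group(g)
    g
  })
}

validate_reference_group <- function(g) {
  if (is.null(g$group_id) || is.null(g$objects) || is.null(g$precipitants))
    ddi_stop("ddi_parse_error",
             "reference group needs group_id, objects and precipitants")
  if (length(g$objects) == 0L || length(g$precipitants) == 0L)
    ddi_stop("ddi_integrity_error",
             "reference group %s has an empty member list", g$group_id)
  if (anyDuplicated(g$objects) || anyDuplicated(g$precipitants))
    ddi_stop("ddi_integrity_error",
             "reference group %s has duplicate member names", g$group_id)
  invisible(g)
}

#' Packaged reference-group fixture
#'
#' Returns the path to the curated reference-group definitions shipped
#' with the package: 12 groups of high-severity interactions whose
#' object x precipitant cross-products expand to 360 unique drug pairs
#' over 86 unique drugs.
#'
#' @return Path to the packaged YAML file.
#' @export
reference_groups_file <- function() {
  system.file("extdata", "reference_groups.yaml", package = "ddicompare",
              mustWork = TRUE)
}

#' Build the reference DDI set from group definitions
#'
#' For each group, every object member is paired with every precipitant
#' member. Pairs whose two members normalize to the same name are
#' excluded; pairs duplicated across groups (compared on normalized,
#' order-insensitive names) are emitted once. When a terminology is
#' supplied, pairs with a member that resolves to a multi-ingredient
#' clinical drug are dropped with a warning, since such members are not
#' consistently representable at the single-ingredient level.
#'
#' @param groups List of reference groups (see
#'   [read_reference_groups()]).
#' @param term Optional `ddi_terminology` used for the
#'   multi-ingredient-member check.
#' @return A `ddi_raw` data frame with `source = "REFERENCE"`, one row
#'   per unique unordered pair.
#' @export
build_reference_set <- function(groups, term = NULL) {
  lapply(groups, validate_reference_group)
  rows <- lapply(groups, function(g) {
    expand.grid(drug_a_name = g$objects, drug_b_name = g$precipitants,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L)
    return(raw_ddi_frame(character(), character(), character()))

  na_ <- normalize_name(rows$drug_a_name)
  nb_ <- normalize_name(rows$drug_b_name)
  rows <- rows[na_ != nb_, , drop = FALSE]
  na_ <- normalize_name(rows$drug_a_name)
  nb_ <- normalize_name(rows$drug_b_name)
  key <- paste(pmin(na_, nb_), pmax(na_, nb_), sep = "\x1f")
  rows <- rows[!duplicated(key), , drop = FALSE]

  if (!is.null(term)) {
    is_multi <- function(nm) {
      cid <- lookup(term, nm)
      if (is.na(cid)) return(FALSE)
      tt <- term_type_of(term, cid)
      tt == "CLINICAL_DRUG" && length(ingredients_of(term, cid)) >= 2L
    }
    multi_a <- vapply(rows$drug_a_name, is_multi, logical(1))
    multi_b <- vapply(rows$drug_b_name, is_multi, logical(1))
    drop <- multi_a | multi_b
    if (any(drop)) {
      warning(sprintf(
        "dropping %d reference pair(s) involving multi-ingredient drugs",
        sum(drop)), call. = FALSE)
      rows <- rows[!drop, , drop = FALSE]
    }
  }
  raw_ddi_frame("REFERENCE", rows$drug_a_name, rows$drug_b_name)
}

#' Serialize and re-read raw DDI lists
#'
#' Round-trippable TSV serialization of a raw DDI table, used for
#' lossless-ingest checks and intermediate storage.
#'
#' @param raw A `ddi_raw` data frame.
#' @param path Output path.
#' @return `path`, invisibly (for `write_raw_ddis`); a `ddi_raw` frame
#'   (for `read_raw_ddis`).
#' @export
write_raw_ddis <- function(raw, path) {
  utils::write.table(as.data.frame(raw), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_raw_ddis
#' @export
read_raw_ddis <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  df$severity[!nzchar(df$severity)] <- NA_character_
  df$description[!nzchar(df$description)] <- NA_character_
  structure(df, class = c("ddi_raw", "data.frame"))
}
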