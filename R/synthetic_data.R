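# Synthetic study-condition generator: a drug terminology with salts,
# multi-ingredient and topical clinical drugs, two DDI sources with a
# planted overlap and salt-form name noise, reference groups, and
# patient prescription lists with known matched-pair frequencies.
# Every generated bundle comes with an exact ground-truth ledger, so
# pipeline recovery tests are set-level equalities, not statistical
# checks.

SALT_SUFFIXES <- c("hydrochloride", "sulfate", "acetate", "sodium",
                   "citrate", "maleate", "tartrate")

# Deterministic pseudo-drug names: the i-th name is the mixed-radix
# decomposition of i over syllable tables, so names are unique by
# construction and free of punctuation.
synth_ingredient_names <- function(n) {
  a <- c("al", "be", "cor", "dal", "en", "fi", "gan", "hy", "il", "jo",
         "ka", "lu", "mi", "nor", "ol", "pra", "qui", "ro", "su", "ta")
  b <- c("ba", "ce", "di", "fe", "gi", "ho", "ju", "ke", "li", "mo",
         "ne", "pi", "ru", "se", "ti", "vo", "wa", "xe", "yo", "zu")
  d <- c("mab", "nib", "olol", "pril", "sartan", "statin", "zole",
         "cillin", "mycin", "oxetine")
  stopifnot(n <= length(a) * length(b) * length(d))
  i <- seq_len(n) - 1L
  paste0(a[(i %/% (length(b) * length(d))) + 1L],
         b[((i %/% length(d)) %% length(b)) + 1L],
         d[(i %% length(d)) + 1L])
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the package is exercised
#' under at desk scale: two sources of similar size with roughly 30%
#' mutual overlap, a two-level severity mix on the tabular source, salt
#' redundancy and unmappable names at rates comparable to real
#' ingredient-level interaction lists, and prescription lists a few
#' drugs long with a modest topical fraction.
#'
#' @param seed Integer RNG seed; every random choice flows from it.
#' @param n_ingredients Number of base ingredients in the terminology.
#' @param salt_rate Fraction of ingredients given one precise-ingredient
#'   (salt) form.
#' @param multi_ingredient_rate Fraction (of `n_ingredients`) of extra
#'   two-ingredient clinical drugs added beyond the one
#'   single-ingredient systemic drug every ingredient gets.
#' @param topical_rate Fraction of ingredients additionally given a
#'   topical clinical drug.
#' @param n_atc_classes Number of 4th-level ATC classes.
#' @param classes_per_ingredient Classes assigned to each ATC-covered
#'   ingredient.
#' @param atc_coverage Fraction of ingredients represented in ATC.
#' @param size_a,size_b Normalized sizes of the two planted DDI sources
#'   (source A is the severity-annotated tabular source, source B the
#'   XML source).
#' @param planted_overlap Number of canonical pairs shared by the two
#'   sources; must not exceed `min(size_a, size_b)`.
#' @param salt_noise_rate Fraction of source records duplicated once
#'   more under a salt-form name (the duplicates collapse away during
#'   normalization).
#' @param critical_fraction Fraction of source-A pairs labeled
#'   `CRITICAL` (the rest are `SIGNIFICANT`).
#' @param unmapped_rate Fraction of extra records per source carrying a
#'   name absent from the terminology (discarded during normalization).
#' @param n_reference_groups Number of reference groups to emit.
#' @param n_patients Number of prescription lists.
#' @param list_length_mean Mean prescription-list length (truncated
#'   geometric, minimum 1).
#' @param planted_pairs Optional named integer vector: canonical pair
#'   key -> target number of dedicated patient lists co-prescribing
#'   that pair (pairs must be drawn from the planted source pairs).
#'   `NULL` lets the generator pick three shared pairs at frequency 5.
#' @return A `ddi_gen_config` list, validated.
#' @export
generator_config <- function(seed = 1L,
                             n_ingredients = 300L,
                             salt_rate = 0.3,
                             multi_ingredient_rate = 0.15,
                             topical_rate = 0.1,
                             n_atc_classes = 12L,
                             classes_per_ingredient = 1L,
                             atc_coverage = 0.85,
                             size_a = 150L,
                             size_b = 150L,
                             planted_overlap = 45L,
                             salt_noise_rate = 0.2,
                             critical_fraction = 0.33,
                             unmapped_rate = 0.05,
                             n_reference_groups = 3L,
                             n_patients = 200L,
                             list_length_mean = 4,
                             planted_pairs = NULL) {
  cfg <- list(seed = as.integer(seed), n_ingredients = as.integer(n_ingredients),
              salt_rate = salt_rate, multi_ingredient_rate = multi_ingredient_rate,
              topical_rate = topical_rate, n_atc_classes = as.integer(n_atc_classes),
              classes_per_ingredient = as.integer(classes_per_ingredient),
              atc_coverage = atc_coverage,
              size_a = as.integer(size_a), size_b = as.integer(size_b),
              planted_overlap = as.integer(planted_overlap),
              salt_noise_rate = salt_noise_rate,
              critical_fraction = critical_fraction,
              unmapped_rate = unmapped_rate,
              n_reference_groups = as.integer(n_reference_groups),
              n_patients = as.integer(n_patients),
              list_length_mean = list_length_mean,
              planted_pairs = planted_pairs)
  rates <- c(cfg$salt_rate, cfg$multi_ingredient_rate, cfg$topical_rate,
             cfg$atc_coverage, cfg$salt_noise_rate, cfg$critical_fraction,
             cfg$unmapped_rate)
  if (any(rates < 0 | rates > 1))
    ddi_stop("ddi_config_error", "generator rates must lie in [0, 1]")
  if (cfg$planted_overlap > min(cfg$size_a, cfg$size_b))
    ddi_stop("ddi_config_error",
             "planted_overlap (%d) exceeds min(size_a, size_b)",
             cfg$planted_overlap)
  max_pairs <- choose(cfg$n_ingredients, 2)
  if (cfg$size_a + cfg$size_b - cfg$planted_overlap > max_pairs)
    ddi_stop("ddi_config_error",
             "requested %d distinct pairs but only %.0f exist for %d ingredients",
             cfg$size_a + cfg$size_b - cfg$planted_overlap, max_pairs,
             cfg$n_ingredients)
  if (cfg$list_length_mean < 1)
    ddi_stop("ddi_config_error", "list_length_mean must be >= 1")
  class(cfg) <- "ddi_gen_config"
  cfg
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Map flat indices 1..choose(n,2) to unordered index pairs (i < j).
index_to_pair <- function(idx, n) {
  # row i (1-based) covers ((i-1)*(2n-i)/2, i*(2n-i-1)/2]
  i <- integer(length(idx))
  j <- integer(length(idx))
  for (k in seq_along(idx)) {
    x <- idx[k]
    ii <- 1L
    row_len <- n - 1L
    while (x > row_len) {
      x <- x - row_len
      ii <- ii + 1L
      row_len <- n - ii
    }
    i[k] <- ii
    j[k] <- ii + x
  }
  cbind(i, j)
}

#' Generate a complete synthetic evaluation bundle
#'
#' Writes a terminology bundle, two raw DDI source files (tabular with
#' severities, XML with descriptions), reference-group YAML, a
#' prescriptions CSV, and a ground-truth ledger JSON into `dir`.
#' Deterministic given `cfg$seed`: two runs with the same configuration
#' produce byte-identical files. Ingesting and normalizing the source
#' files against the generated terminology reproduces the ledger's
#' `true_pairs_a` / `true_pairs_b` exactly; salt-noise records collapse
#' back onto their base pairs; planted out-of-terminology names are
#' counted in `unmapped_records`.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `ledger` (the ground-truth ledger, also written as JSON).
#' @export
generate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "ddi_gen_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_local_seed(cfg$seed, generate_bundle_impl(cfg, dir))
}

generate_bundle_impl <- function(cfg, dir) {
  n <- cfg$n_ingredients
  ing_ids <- sprintf("I%04d", seq_len(n))
  ing_names <- synth_ingredient_names(n)

  ## salts
  has_salt <- stats::runif(n) < cfg$salt_rate
  salt_ids <- sprintf("P%04d", which(has_salt))
  salt_of <- stats::setNames(salt_ids, ing_ids[has_salt])
  salt_names <- paste(ing_names[has_salt],
                      sample(SALT_SUFFIXES, sum(has_salt), replace = TRUE))

  ## clinical drugs: one single-ingredient systemic drug per ingredient,
  ## plus extra multi-ingredient and topical products
  base_drug_ids <- sprintf("D%04d", seq_len(n))
  strengths <- sample(c(5L, 10L, 20L, 25L, 50L, 100L, 250L), n, replace = TRUE)
  base_drug_names <- sprintf("%s %d MG Oral Tablet", ing_names, strengths)
  drug_ing <- stats::setNames(as.list(ing_ids), base_drug_ids)

  n_multi <- round(cfg$multi_ingredient_rate * n)
  multi_ids <- character(0)
  if (n_multi > 0) {
    combo_idx <- sample.int(choose(n, 2), n_multi)
    combos <- index_to_pair(combo_idx, n)
    multi_ids <- sprintf("D%04d", n + seq_len(n_multi))
    multi_names <- sprintf("%s %d MG/%s %d MG Oral Tablet",
                           ing_names[combos[, 1]], strengths[combos[, 1]],
                           ing_names[combos[, 2]], strengths[combos[, 2]])
    for (k in seq_len(n_multi))
      drug_ing[[multi_ids[k]]] <- ing_ids[combos[k, ]]
  } else multi_names <- character(0)

  n_top <- round(cfg$topical_rate * n)
  top_ids <- character(0)
  if (n_top > 0) {
    top_ing <- sample.int(n, n_top)
    top_ids <- sprintf("D%04d", n + n_multi + seq_len(n_top))
    top_names <- sprintf("%s 1 %% Topical Cream", ing_names[top_ing])
    for (k in seq_len(n_top)) drug_ing[[top_ids[k]]] <- ing_ids[top_ing[k]]
  } else top_names <- character(0)

  drug_ids <- c(base_drug_ids, multi_ids, top_ids)
  drug_names <- c(base_drug_names, multi_names, top_names)
  route <- c(rep("SYSTEMIC", n + n_multi), rep("TOPICAL", n_top))

  ## ATC assignments
  atc_codes <- sprintf("%s%02d%s", LETTERS[(seq_len(cfg$n_atc_classes) - 1L) %% 26 + 1L],
                       seq_len(cfg$n_atc_classes) %% 100, "AA")
  covered <- stats::runif(n) < cfg$atc_coverage
  atc_rows <- NULL
  if (cfg$n_atc_classes > 0 && any(covered)) {
    k <- min(cfg$classes_per_ingredient, cfg$n_atc_classes)
    atc_rows <- do.call(rbind, lapply(which(covered), function(i) {
      data.frame(ingredient_id = ing_ids[i],
                 atc_code = sample(atc_codes, k),
                 stringsAsFactors = FALSE)
    }))
    atc_rows$atc_name <- paste("class", atc_rows$atc_code)
  } else {
    atc_rows <- data.frame(ingredient_id = character(), atc_code = character(),
                           atc_name = character(), stringsAsFactors = FALSE)
  }

  ## concept / relation tables
  concepts <- data.frame(
    concept_id = c(ing_ids, salt_ids, drug_ids),
    name = c(ing_names, salt_names, drug_names),
    term_type = c(rep("INGREDIENT", n),
                  rep("PRECISE_INGREDIENT", length(salt_ids)),
                  rep("CLINICAL_DRUG", length(drug_ids))),
    route_class = c(rep("NOT_APPLICABLE", n + length(salt_ids)), route),
    obsolete = 0L,
    stringsAsFactors = FALSE
  )
  relations <- rbind(
    data.frame(rel_type = "has_ingredient_base",
               source_id = unname(salt_of), target_id = names(salt_of),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(drug_ing), function(d)
      data.frame(rel_type = "has_ingredient", source_id = d,
                 target_id = drug_ing[[d]], stringsAsFactors = FALSE)))
  )
  term <- new_terminology(concepts, relations, atc_rows)

  ## planted DDI pairs
  n_distinct <- cfg$size_a + cfg$size_b - cfg$planted_overlap
  pool <- sample.int(choose(n, 2), n_distinct)
  pp <- index_to_pair(pool, n)
  lo <- pmin(ing_ids[pp[, 1]], ing_ids[pp[, 2]])
  hi <- pmax(ing_ids[pp[, 1]], ing_ids[pp[, 2]])
  keys <- pair_key(lo, hi)
  shared_keys <- keys[seq_len(cfg$planted_overlap)]
  a_only <- keys[cfg$planted_overlap + seq_len(cfg$size_a - cfg$planted_overlap)]
  b_only <- keys[cfg$size_a + seq_len(cfg$size_b - cfg$planted_overlap)]
  keys_a <- sort(c(shared_keys, a_only))
  keys_b <- sort(c(shared_keys, b_only))

  sev_a <- stats::setNames(
    ifelse(stats::runif(length(keys_a)) < cfg$critical_fraction,
           "CRITICAL", "SIGNIFICANT"), keys_a)

  name_of <- stats::setNames(concepts$name, concepts$concept_id)
  salt_name_of <- function(iid) {
    sid <- salt_of[iid]
    ifelse(is.na(sid), name_of[iid], name_of[sid])
  }

  ## raw records for one source: base record per pair, plus salt-form
  ## duplicates and unmappable extras
  make_records <- function(keys_s, sev = NULL) {
    pr <- split_pair_key(keys_s)
    rec <- data.frame(a = unname(name_of[pr$low_id]),
                      b = unname(name_of[pr$high_id]),
                      severity = if (is.null(sev)) NA_character_ else unname(sev),
                      stringsAsFactors = FALSE)
    can_salt <- pr$low_id %in% names(salt_of) | pr$high_id %in% names(salt_of)
    dup <- can_salt & stats::runif(nrow(pr)) < cfg$salt_noise_rate
    extra <- data.frame(a = unname(salt_name_of(pr$low_id[dup])),
                        b = unname(salt_name_of(pr$high_id[dup])),
                        severity = rec$severity[dup],
                        stringsAsFactors = FALSE)
    n_unm <- round(cfg$unmapped_rate * length(keys_s))
    unm <- data.frame(a = sprintf("zzq unknowndrug %04d", sample.int(9999L, n_unm)),
                      b = unname(name_of[sample(ing_ids, n_unm)]),
                      severity = if (is.null(sev)) rep(NA_character_, n_unm) else
                        sample(SEVERITIES, n_unm, replace = TRUE),
                      stringsAsFactors = FALSE)
    all_rec <- rbind(rec, extra, unm)
    perm <- sample.int(nrow(all_rec))
    list(records = all_rec[perm, , drop = FALSE],
         salt_redundant = sum(dup), unmapped = n_unm)
  }
  rec_a <- make_records(keys_a, sev_a)
  rec_b <- make_records(keys_b)

  paths <- list(
    concepts = file.path(dir, "concepts.tsv"),
    relations = file.path(dir, "relations.tsv"),
    atc = file.path(dir, "atc.tsv"),
    ndfrt = file.path(dir, "source_ndfrt.tsv"),
    drugbank = file.path(dir, "source_drugbank.xml"),
    reference = file.path(dir, "reference_groups.yaml"),
    prescriptions = file.path(dir, "prescriptions.csv"),
    ledger = file.path(dir, "ledger.json")
  )
  wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE, na = "")
  wt(concepts, paths$concepts)
  wt(relations, paths$relations)
  wt(atc_rows, paths$atc)
  wt(data.frame(drug_a = rec_a$records$a, drug_b = rec_a$records$b,
                severity = tolower(rec_a$records$severity),
                stringsAsFactors = FALSE), paths$ndfrt)
  write_drugbank_xml(rec_b$records, paths$drugbank)

  ## reference groups over ingredients untouched by salts (names map 1:1)
  ref_pool <- sample(ing_ids, min(n, cfg$n_reference_groups * 8L))
  groups <- list()
  used <- 0L
  for (g in seq_len(cfg$n_reference_groups)) {
    n_obj <- sample(1:2, 1L)
    n_pre <- sample(2:4, 1L)
    if (used + n_obj + n_pre > length(ref_pool)) break
    members <- ref_pool[used + seq_len(n_obj + n_pre)]
    used <- used + n_obj + n_pre
    groups[[length(groups) + 1L]] <- list(
      group_id = g, label = sprintf("synthetic group %d", g),
      objects = as.list(unname(name_of[members[seq_len(n_obj)]])),
      precipitants = as.list(unname(name_of[members[n_obj + seq_len(n_pre)]])))
  }
  yaml::write_yaml(groups, paths$reference)
  ref_pair_count <- sum(vapply(groups, function(g)
    length(g$objects) * length(g$precipitants), numeric(1)))

  ## prescriptions: random background lists plus dedicated lists that
  ## co-prescribe the planted pairs at their target frequencies
  planted <- cfg$planted_pairs
  if (is.null(planted)) {
    k <- min(3L, length(shared_keys))
    planted <- stats::setNames(rep(5L, k), shared_keys[seq_len(k)])
  }
  drug_of_ing <- stats::setNames(base_drug_ids, ing_ids)
  rows <- list()
  for (p in seq_len(cfg$n_patients)) {
    len <- min(1L + stats::rgeom(1L, 1 / cfg$list_length_mean), 10L)
    rows[[p]] <- data.frame(
      patient_id = sprintf("pt%05d", p),
      drug_id = sample(drug_ids, min(len, length(drug_ids))),
      count = 1L, stringsAsFactors = FALSE)
  }
  pi_ <- cfg$n_patients
  for (k in names(planted)) {
    pr <- split_pair_key(k)
    for (r in seq_len(planted[[k]])) {
      pi_ <- pi_ + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("pt%05d", pi_),
        drug_id = unname(c(drug_of_ing[pr$low_id], drug_of_ing[pr$high_id])),
        count = 1L, stringsAsFactors = FALSE)
    }
  }
  presc <- do.call(rbind, rows)
  utils::write.csv(presc, paths$prescriptions, row.names = FALSE, quote = FALSE)

  ## ground-truth ledger; the screening recount is an independent
  ## nested-loop tally over the emitted CSV rows
  recount <- recount_screening(presc, drug_ing,
                               stats::setNames(route, drug_ids),
                               list(A = keys_a, B = keys_b))
  sev_strata <- split(names(sev_a), unname(sev_a))
  expected_sev_cov <- vapply(sev_strata, function(ks)
    round_percent(length(intersect(ks, keys_b)), length(ks)), integer(1))

  ledger <- list(
    true_pairs_a = keys_a, true_pairs_b = keys_b,
    true_overlap = length(intersect(keys_a, keys_b)),
    severity_of_a = as.list(sev_a),
    salt_redundant_records = list(A = rec_a$salt_redundant,
                                  B = rec_b$salt_redundant),
    unmapped_records = list(A = rec_a$unmapped, B = rec_b$unmapped),
    expected_severity_coverage = as.list(expected_sev_cov),
    reference_pair_count = ref_pair_count,
    planted_pairs = as.list(planted),
    screening = recount
  )
  jsonlite::write_json(ledger, paths$ledger, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, ledger = ledger))
}

# Straightforward nested-loop recount of screening totals, kept
# deliberately separate from screen()'s streaming implementation.
recount_screening <- function(presc, drug_ing, route_of, source_keys) {
  tally <- new.env(parent = emptyenv())
  for (pid in unique(presc$patient_id)) {
    block <- presc[presc$patient_id == pid, , drop = FALSE]
    drugs <- unique(block$drug_id)
    drugs <- drugs[route_of[drugs] != "TOPICAL"]
    w <- as.integer(block$count[1])
    if (length(drugs) < 2L) next
    seen <- character()
    for (i in seq_len(length(drugs) - 1L)) {
      for (j in seq(i + 1L, length(drugs))) {
        for (x in drug_ing[[drugs[i]]]) for (y in drug_ing[[drugs[j]]]) {
          if (x == y) next
          k <- pair_key(min(x, y), max(x, y))
          if (k %in% seen) next
          seen <- c(seen, k)
          tally[[k]] <- (tally[[k]] %||% 0L) + w
        }
      }
    }
  }
  pf <- unlist(as.list(tally))
  if (is.null(pf)) pf <- stats::setNames(integer(), character())
  per_source <- lapply(source_keys, function(ks) {
    hit <- names(pf) %in% ks
    list(total = sum(pf[hit]), unique = sum(hit))
  })
  both_keys <- Reduce(intersect, source_keys)
  hit <- names(pf) %in% both_keys
  list(total_pairs = sum(pf), unique_pairs = length(pf),
       per_source = per_source,
       both_sources = list(total = sum(pf[hit]), unique = sum(hit)),
       pair_frequency = as.list(pf[order(names(pf))]))
}

# Writer for the XML dialect read by read_drugbank_xml(): records
# grouped by their first drug name.
write_drugbank_xml <- function(records, path) {
  doc <- xml2::xml_new_root("drugbank")
  first <- factor(records$a, levels = unique(records$a))
  blocks <- split(records, first)
  did <- 0L
  for (a in names(blocks)) {
    did <- did + 1L
    drug <- xml2::xml_add_child(doc, "drug")
    xml2::xml_add_child(drug, "drugbank-id", sprintf("SYN%05d", did))
    xml2::xml_add_child(drug, "name", a)
    ints <- xml2::xml_add_child(drug, "drug-interactions")
    blk <- blocks[[a]]
    for (r in seq_len(nrow(blk))) {
      int <- xml2::xml_add_child(ints, "drug-interaction")
      xml2::xml_add_child(int, "drugbank-id", sprintf("SYN%05d-%d", did, r))
      xml2::xml_add_child(int, "name", blk$b[r])
      xml2::xml_add_child(int, "description",
                          sprintf("%s may alter the effect of %s.", a, blk$b[r]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
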