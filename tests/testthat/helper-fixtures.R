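# Shared fixtures: a small hand-built terminology exercising salts,
# multi-ingredient and topical clinical drugs, obsolete concepts and
# partial ATC coverage; plus brute-force oracles used against the
# implementation on random inputs.

tiny_concepts <- function() {
  data.frame(
    concept_id = c("I01", "I02", "I03", "I04", "I05", "I06", "I07", "I08",
                   "I09", "I10", "I11",
                   "P01", "P02", "P03", "P04",
                   "D01", "D02", "D03", "D04"),
    name = c("doxacurium", "zuclopenthixol", "omeprazole", "clopidogrel",
             "Primidone", "Carbidopa", "Levodopa", "Diltiazem",
             "Lovastatin", "avanafil", "oldine",
             "doxacurium chloride", "zuclopenthixol acetate",
             "zuclopenthixol deconoate", "clopidogrel bisulfate",
             "Primidone 250 MG Oral Tablet",
             "Carbidopa 25 MG/Levodopa 100 MG Oral Tablet",
             "Diltiazem 2 % Topical Cream",
             "Lovastatin 20 MG Oral Tablet"),
    term_type = c(rep("INGREDIENT", 11), rep("PRECISE_INGREDIENT", 4),
                  rep("CLINICAL_DRUG", 4)),
    route_class = c(rep("NOT_APPLICABLE", 15),
                    "SYSTEMIC", "SYSTEMIC", "TOPICAL", "SYSTEMIC"),
    obsolete = c(rep(0L, 10), 1L, rep(0L, 8)),
    stringsAsFactors = FALSE
  )
}

tiny_relations <- function() {
  data.frame(
    rel_type = c(rep("has_ingredient_base", 4), rep("has_ingredient", 5)),
    source_id = c("P01", "P02", "P03", "P04", "D01", "D02", "D02", "D03", "D04"),
    target_id = c("I01", "I02", "I02", "I04", "I05", "I06", "I07", "I08", "I09"),
    stringsAsFactors = FALSE
  )
}

tiny_atc <- function() {
  data.frame(
    ingredient_id = c("I04", "I08", "I09", "I02", "I02"),
    atc_code = c("B01AC", "C08DB", "C10AA", "N05AF", "N05AX"),
    atc_name = c("Platelet aggregation inhibitors", "Benzothiazepine derivatives",
                 "HMG CoA reductase inhibitors", "Thioxanthene derivatives",
                 "Other antipsychotics"),
    stringsAsFactors = FALSE
  )
}

tiny_term <- function() new_terminology(tiny_concepts(), tiny_relations(), tiny_atc())

write_tiny_bundle <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(concepts = file.path(dir, "concepts.tsv"),
                relations = file.path(dir, "relations.tsv"),
                atc = file.path(dir, "atc.tsv"))
  wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(tiny_concepts(), paths$concepts)
  wt(tiny_relations(), paths$relations)
  wt(tiny_atc(), paths$atc)
  paths
}

# A larger purely-ingredient terminology for random-set tests.
flat_term <- function(n = 60, n_classes = 6, classes_per = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("I%03d", seq_len(n))
  concepts <- data.frame(concept_id = ids,
                         name = paste0("ing", seq_len(n)),
                         term_type = "INGREDIENT",
                         route_class = "NOT_APPLICABLE",
                         obsolete = 0L, stringsAsFactors = FALSE)
  atc <- data.frame(ingredient_id = character(), atc_code = character(),
                    atc_name = character(), stringsAsFactors = FALSE)
  if (n_classes > 0) {
    codes <- sprintf("A%02dAA", seq_len(n_classes))
    atc <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(ingredient_id = ids[i],
                 atc_code = sample(codes, classes_per),
                 atc_name = "x", stringsAsFactors = FALSE)))
  }
  new_terminology(concepts, atc = atc)
}

random_pair_keys <- function(ids, k) {
  stopifnot(k <= choose(length(ids), 2))
  keys <- character(0)
  while (length(keys) < k) {
    pick <- sample(ids, 2)
    keys <- unique(c(keys, paste(min(pick), max(pick), sep = "\x1f")))
  }
  keys[seq_len(k)]
}

set_from_keys <- function(keys, source = "OTHER", severity = NA_character_) {
  parts <- strsplit(keys, "\x1f", fixed = TRUE)
  new_ddi_set(source,
              vapply(parts, `[`, character(1), 1L),
              vapply(parts, `[`, character(1), 2L),
              severity = severity)
}

# Brute-force overlap: nested-loop membership counting.
brute_overlap <- function(keys_a, keys_b) {
  shared <- 0L
  for (k in keys_a) for (j in keys_b) if (k == j) shared <- shared + 1L
  list(shared = shared, only_a = length(keys_a) - shared,
       only_b = length(keys_b) - shared)
}

# Brute-force class-pair table: enumerate every DDI x class-combination.
brute_class_pairs <- function(set, term) {
  out <- list()
  for (i in seq_len(nrow(set$pairs))) {
    ca <- atc_classes(term, set$pairs$low_id[i])
    cb <- atc_classes(term, set$pairs$high_id[i])
    if (length(ca) == 0 || length(cb) == 0) next
    key <- paste(set$pairs$low_id[i], set$pairs$high_id[i], sep = "\x1f")
    for (x in ca) for (y in cb) {
      ck <- paste(min(x, y), max(x, y), sep = "\x1e")
      out[[ck]] <- unique(c(out[[ck]], key))
    }
  }
  out
}
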