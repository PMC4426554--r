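test_that("canonical pairs are symmetric, ordered, and reject self-pairs", {
  cp <- canonical_pair("lovastatin-id", "diltiazem-id")
  expect_equal(cp$low_id, "diltiazem-id")
  expect_equal(cp$high_id, "lovastatin-id")

  set.seed(5)
  for (i in 1:20) {
    ab <- sprintf("I%03d", sample(1:999, 2))
    expect_identical(canonical_pair(ab[1], ab[2]), canonical_pair(ab[2], ab[1]))
  }
  expect_error(canonical_pair("a", "a"), class = "ddi_self_pair_error")
})

test_that("salt forms collapse to one ingredient pair with counted duplicates", {
  term <- tiny_term()
  raw <- raw_ddi_frame("DRUGBANK", rep("omeprazole", 3),
                       c("zuclopenthixol", "zuclopenthixol acetate",
                         "zuclopenthixol deconoate"))
  res <- normalize_ddi_list(raw, term)
  expect_equal(nrow(res$set$pairs), 1L)
  expect_equal(res$set$pairs$low_id, "I02")
  expect_equal(res$set$pairs$high_id, "I03")
  expect_equal(res$report$collapsed_duplicates, 2L)
  expect_equal(res$report$output_size, 1L)
})

test_that("records with unmappable names are discarded and counted", {
  term <- tiny_term()
  raw <- raw_ddi_frame("DRUGBANK",
                       c("cerivastatin", "oldine", "Lovastatin"),
                       c("omeprazole", "omeprazole", "Diltiazem"))
  res <- normalize_ddi_list(raw, term)
  # cerivastatin absent; oldine obsolete, treated as unmapped
  expect_equal(res$report$unmapped_ddis, 2L)
  expect_equal(res$report$unmapped_drugs, 2L)
  expect_equal(res$report$output_size, 1L)
})

test_that("distinct mappable base-ingredient pairs pass through unchanged", {
  term <- flat_term(n = 30, n_classes = 0)
  keys <- local({set.seed(8); random_pair_keys(term$concepts$concept_id, 12)})
  pr <- split_pair_key(keys)
  nm <- stats::setNames(term$concepts$name, term$concepts$concept_id)
  raw <- raw_ddi_frame("OTHER", nm[pr$low_id], nm[pr$high_id])
  res <- normalize_ddi_list(raw, term)
  expect_equal(res$report$output_size, 12L)
  expect_equal(res$report$unmapped_ddis +  res$report$collapsed_duplicates +
                 res$report$self_pairs_dropped + res$report$multi_ingredient_dropped,
               0L)
  expect_setequal(ddi_set_keys(res$set), keys)
})

test_that("self-pairs and clinical-drug names take their own discard paths", {
  term <- tiny_term()
  raw <- raw_ddi_frame("DRUGBANK",
                       c("zuclopenthixol acetate", "Primidone 250 MG Oral Tablet"),
                       c("zuclopenthixol deconoate", "Lovastatin"))
  res <- normalize_ddi_list(raw, term)
  expect_equal(res$report$self_pairs_dropped, 1L)
  expect_equal(res$report$multi_ingredient_dropped, 1L)
  expect_equal(res$report$output_size, 0L)
})

test_that("severity conflicts on merge keep the maximum severity", {
  term <- tiny_term()
  raw <- raw_ddi_frame("NDFRT",
                       c("omeprazole", "omeprazole"),
                       c("clopidogrel", "clopidogrel bisulfate"),
                       severity = c("SIGNIFICANT", "CRITICAL"))
  res <- normalize_ddi_list(raw, term)
  expect_equal(nrow(res$set$pairs), 1L)
  expect_equal(res$set$pairs$severity, "CRITICAL")
})

test_that("mixed source tags are a contract error", {
  raw <- rbind(raw_ddi_frame("NDFRT", "a", "b", severity = "CRITICAL"),
               raw_ddi_frame("DRUGBANK", "c", "d"))
  expect_error(normalize_ddi_list(raw, tiny_term()), class = "ddi_contract_error")
})

test_that("normalization is idempotent and order-insensitive", {
  cfg <- generator_config(seed = 21, n_ingredients = 80, size_a = 60,
                          size_b = 60, planted_overlap = 20)
  b <- generate_bundle(cfg, withr::local_tempdir())
  term <- load_terminology(b$paths$concepts, b$paths$relations, b$paths$atc)
  raw <- read_ndfrt_records(b$paths$ndfrt)
  res <- normalize_ddi_list(raw, term)

  # idempotence: re-normalizing the serialized output is an all-zero pass
  again <- normalize_ddi_list(ddi_set_to_raw(res$set, term), term)
  expect_identical(again$set$pairs, res$set$pairs)
  expect_equal(again$report$unmapped_ddis, 0L)
  expect_equal(again$report$collapsed_duplicates, 0L)
  expect_equal(again$report$self_pairs_dropped, 0L)
  expect_equal(again$report$multi_ingredient_dropped, 0L)

  # order-insensitivity: permuting the raw list leaves the set identical
  perm <- local({set.seed(99); sample.int(nrow(raw))})
  res2 <- normalize_ddi_list(raw[perm, ], term)
  expect_identical(res2$set$pairs, res$set$pairs)
  expect_identical(unclass(res2$report), unclass(res$report))
})

test_that("the report conservation equation holds on generated sources", {
  for (seed in c(101, 202, 303)) {
    cfg <- generator_config(seed = seed, n_ingredients = 70, size_a = 50,
                            size_b = 40, planted_overlap = 10,
                            salt_noise_rate = 0.4, unmapped_rate = 0.15)
    b <- generate_bundle(cfg, withr::local_tempdir())
    term <- load_terminology(b$paths$concepts, b$paths$relations, b$paths$atc)
    for (raw in list(read_ndfrt_records(b$paths$ndfrt),
                     read_drugbank_xml(b$paths$drugbank))) {
      rep_ <- normalize_ddi_list(raw, term)$report
      expect_equal(rep_$output_size,
                   rep_$total_input - rep_$unmapped_ddis -
                     rep_$collapsed_duplicates - rep_$self_pairs_dropped -
                     rep_$multi_ingredient_dropped)
      expect_equal(rep_$total_input, nrow(raw))
    }
  }
})

test_that("normalized sets serialize to TSV and back", {
  term <- tiny_term()
  raw <- raw_ddi_frame("NDFRT", c("omeprazole", "Diltiazem"),
                       c("clopidogrel", "Lovastatin"),
                       severity = c("CRITICAL", "SIGNIFICANT"))
  set <- normalize_ddi_list(raw, term)$set
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ddi_set(set, path)
  back <- read_ddi_set(path, source = "NDFRT")
  expect_identical(back$pairs, set$pairs)
})
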