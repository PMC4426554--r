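drugbank_fixture_xml <- function(path, drugs) {
  # drugs: list(list(name=, partners=data.frame(name, description)), ...)
  doc <- xml2::xml_new_root("drugbank")
  for (i in seq_along(drugs)) {
    d <- xml2::xml_add_child(doc, "drug")
    xml2::xml_add_child(d, "drugbank-id", sprintf("DB%05d", i))
    xml2::xml_add_child(d, "name", drugs[[i]]$name)
    ints <- xml2::xml_add_child(d, "drug-interactions")
    p <- drugs[[i]]$partners
    for (r in seq_len(NROW(p))) {
      int <- xml2::xml_add_child(ints, "drug-interaction")
      xml2::xml_add_child(int, "drugbank-id", sprintf("DB%05d", 1000 + r))
      xml2::xml_add_child(int, "name", p$name[r])
      xml2::xml_add_child(int, "description", p$description[r])
    }
  }
  xml2::write_xml(doc, path)
  path
}

test_that("the XML reader emits one record per interaction element", {
  path <- withr::local_tempfile(fileext = ".xml")
  desc <- "Omeprazole may decrease serum concentrations of the active metabolite(s) of clopidogrel."
  drugbank_fixture_xml(path, list(list(
    name = "omeprazole",
    partners = data.frame(name = "clopidogrel bisulfate", description = desc,
                          stringsAsFactors = FALSE))))
  raw <- read_drugbank_xml(path)
  expect_equal(nrow(raw), 1L)
  expect_equal(raw$drug_a_name, "omeprazole")
  expect_equal(raw$drug_b_name, "clopidogrel bisulfate")
  expect_equal(raw$description, desc)
  expect_true(all(is.na(raw$severity)))
  expect_equal(unique(raw$source), "DRUGBANK")
})

test_that("the XML reader handles empty files and counts planted interactions", {
  path <- withr::local_tempfile(fileext = ".xml")
  drugbank_fixture_xml(path, list(list(name = "lonelydrug",
                                       partners = data.frame(name = character(),
                                                             description = character()))))
  expect_equal(nrow(read_drugbank_xml(path)), 0L)

  set.seed(11)
  n <- 17L
  partners <- data.frame(name = sprintf("partner%02d", seq_len(n)),
                         description = sprintf("desc %d", seq_len(n)),
                         stringsAsFactors = FALSE)
  drugbank_fixture_xml(path, list(list(name = "hubdrug", partners = partners)))
  expect_equal(nrow(read_drugbank_xml(path)), n)

  writeLines("<drugbank><drug>", path)
  expect_error(read_drugbank_xml(path), class = "ddi_parse_error")
})

test_that("the tabular reader parses severities and rejects unknown tokens", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_a\tdrug_b\tseverity",
               "omeprazole\tclopidogrel\tcritical",
               "diltiazem\tlovastatin\tSignificant"), path)
  raw <- read_ndfrt_records(path)
  expect_equal(raw$severity, c("CRITICAL", "SIGNIFICANT"))
  expect_equal(unique(raw$source), "NDFRT")

  writeLines("drug_a\tdrug_b\tseverity", path)
  expect_equal(nrow(read_ndfrt_records(path)), 0L)

  writeLines(c("drug_a\tdrug_b\tseverity", "a\tb\tsevere"), path)
  expect_error(read_ndfrt_records(path), "severe", class = "ddi_value_error")

  writeLines(c("drug_a\tdrug_b", "a\tb"), path)
  expect_error(read_ndfrt_records(path), class = "ddi_parse_error")
})

test_that("raw DDI lists survive a serialize/re-read round trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  raw <- raw_ddi_frame("NDFRT", c("alpha", "beta"), c("gamma", "delta"),
                       severity = c("CRITICAL", "SIGNIFICANT"))
  write_raw_ddis(raw, path)
  back <- read_raw_ddis(path)
  expect_equal(as.data.frame(back), as.data.frame(raw))
})

test_that("reference-set construction is the deduplicated cross-product", {
  g <- list(group_id = 4, label = "PPI block", objects = "Atazanavir",
            precipitants = c("Omeprazole", "Lansoprazole", "Pantoprazole",
                             "Rabeprazole", "Esmoprazole"))
  expect_equal(nrow(build_reference_set(list(g))), 5L)

  # m objects x n disjoint precipitants -> m*n pairs, against brute force
  set.seed(3)
  for (rep in 1:10) {
    m <- sample(1:5, 1); n <- sample(1:6, 1)
    nm <- sprintf("syn%03d", sample(1:500, m + n))
    g <- list(group_id = 1, label = "r", objects = nm[seq_len(m)],
              precipitants = nm[m + seq_len(n)])
    expect_equal(nrow(build_reference_set(list(g))), m * n)
  }

  # self-pairs excluded, duplicates across groups collapse
  g1 <- list(group_id = 1, label = "a", objects = c("x", "y"),
             precipitants = c("y", "z"))
  g2 <- list(group_id = 2, label = "b", objects = "z",
             precipitants = c("X", "y"))   # (x,z) already in g1 modulo case+order
  ref <- build_reference_set(list(g1, g2))
  keys <- paste(pmin(normalize_name(ref$drug_a_name), normalize_name(ref$drug_b_name)),
                pmax(normalize_name(ref$drug_a_name), normalize_name(ref$drug_b_name)))
  expect_false(any(duplicated(keys)))
  expect_equal(nrow(ref), 3L)  # xy, xz, yz; self yy dropped; zX, zy are dups
})

test_that("reference pairs touching multi-ingredient drugs are dropped with a warning", {
  term <- tiny_term()
  g <- list(group_id = 1, label = "m",
            objects = "Carbidopa 25 MG/Levodopa 100 MG Oral Tablet",
            precipitants = c("Primidone", "Lovastatin"))
  expect_warning(ref <- build_reference_set(list(g), term), "multi-ingredient")
  expect_equal(nrow(ref), 0L)
})

test_that("the packaged reference fixture expands to 360 unique pairs over 86 drugs", {
  groups <- read_reference_groups(reference_groups_file())
  expect_length(groups, 12)
  ref <- build_reference_set(groups)
  expect_equal(nrow(ref), 360L)
  expect_equal(length(unique(normalize_name(c(ref$drug_a_name, ref$drug_b_name)))),
               86L)
})
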