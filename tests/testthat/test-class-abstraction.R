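test_that("DDIs abstract to unordered class pairs with multi-class fan-out", {
  term <- tiny_term()
  # zuclopenthixol (2 classes) x clopidogrel (1 class) -> 2 class pairs
  s <- new_ddi_set("NDFRT", "I02", "I04", severity = "CRITICAL")
  m <- abstract_to_class_pairs(s, term)
  expect_setequal(names(m), c(class_pair_key("N05AF", "B01AC"),
                              class_pair_key("N05AX", "B01AC")))
  expect_equal(attr(m, "excluded"), 0L)

  # an ATC-less member excludes the DDI and counts it
  s2 <- set_from_keys(pair_key("I03", "I04"), "NDFRT")  # omeprazole has no class
  m2 <- abstract_to_class_pairs(s2, term)
  expect_length(m2, 0)
  expect_equal(attr(m2, "excluded"), 1L)

  # 2 classes x 3 classes -> 6 class pairs (brute-force enumeration)
  cc <- data.frame(concept_id = c("I1", "I2"), name = c("alpha", "beta"),
                   term_type = "INGREDIENT", route_class = "NOT_APPLICABLE",
                   obsolete = 0L)
  atc <- data.frame(ingredient_id = c("I1", "I1", "I2", "I2", "I2"),
                    atc_code = c("A01AA", "A02AA", "B01AA", "B02AA", "B03AA"),
                    atc_name = "x")
  t2 <- new_terminology(cc, atc = atc)
  m3 <- abstract_to_class_pairs(new_ddi_set("OTHER", "I1", "I2"), t2)
  expect_length(m3, 6)
})

test_that("class profiles count distinct DDIs and member drugs per class", {
  term <- flat_term(n = 40, n_classes = 5, seed = 1)
  set.seed(23)
  s <- set_from_keys(random_pair_keys(term$concepts$concept_id, 50), "NDFRT")
  prof <- class_profiles(s, term)
  expect_true(all(prof$drug_count >= 1 | prof$ddi_count == 0))

  # brute-force recount
  for (r in seq_len(nrow(prof))) {
    cl <- prof$atc_code[r]
    ddis <- 0L; drugs <- character()
    for (i in seq_len(nrow(s$pairs))) {
      in_lo <- cl %in% atc_classes(term, s$pairs$low_id[i])
      in_hi <- cl %in% atc_classes(term, s$pairs$high_id[i])
      if (in_lo || in_hi) {
        ddis <- ddis + 1L
        if (in_lo) drugs <- union(drugs, s$pairs$low_id[i])
        if (in_hi) drugs <- union(drugs, s$pairs$high_id[i])
      }
    }
    expect_equal(prof$ddi_count[r], ddis)
    expect_equal(prof$drug_count[r], length(drugs))
  }

  empty <- new_ddi_set("NDFRT", character(), character())
  expect_equal(nrow(class_profiles(empty, term)), 0L)
})

test_that("published-scale component counts reproduce the printed Jaccard scores", {
  # build class-pair maps carrying the printed only/shared component counts
  mk <- function(cls, only_a, only_b, shared) {
    keys <- sprintf("X%04d\x1fY%04d", seq_len(only_a + only_b + shared),
                    seq_len(only_a + only_b + shared))
    a <- keys[seq_len(only_a + shared)]
    b <- keys[c(seq_len(shared), only_a + shared + seq_len(only_b))]
    list(a = stats::setNames(list(a), cls), b = stats::setNames(list(b), cls))
  }
  m1 <- mk(class_pair_key("J05AE", "L01EA"), only_a = 72, only_b = 10, shared = 21)
  j1 <- class_pair_jaccard(m1$a, m1$b)
  expect_equal(j1$total, 103L)
  expect_equal(round(j1$jaccard, 2), 0.20)

  m2 <- mk(class_pair_key("C07AA", "A10BB"), only_a = 10, only_b = 14, shared = 32)
  j2 <- class_pair_jaccard(m2$a, m2$b)
  expect_equal(j2$total, 56L)
  expect_equal(round(j2$jaccard, 2), 0.57)
})

test_that("class-pair Jaccard matches a brute-force oracle on random fixtures", {
  term <- flat_term(n = 40, n_classes = 6, classes_per = 2, seed = 2)
  set.seed(41)
  for (i in 1:6) {
    ka <- random_pair_keys(term$concepts$concept_id, sample(20:60, 1))
    kb <- random_pair_keys(term$concepts$concept_id, sample(20:60, 1))
    sa <- set_from_keys(ka, "NDFRT"); sb <- set_from_keys(kb, "DRUGBANK")
    ma <- abstract_to_class_pairs(sa, term)
    mb <- abstract_to_class_pairs(sb, term)
    bfa <- brute_class_pairs(sa, term)
    bfb <- brute_class_pairs(sb, term)
    expect_setequal(names(ma), names(bfa))
    for (k in names(ma)) expect_setequal(ma[[k]], bfa[[k]])

    jac <- class_pair_jaccard(ma, mb)
    for (r in seq_len(nrow(jac))) {
      k <- class_pair_key(jac$class_a[r], jac$class_b[r])
      bf <- brute_overlap(unique(bfa[[k]]) %||% character(),
                          unique(bfb[[k]]) %||% character())
      expect_equal(jac$shared[r], bf$shared)
      expect_equal(jac$only_a[r], bf$only_a)
      expect_equal(jac$only_b[r], bf$only_b)
    }
    expect_true(all(jac$jaccard >= 0 & jac$jaccard <= 1))
    expect_true(all((jac$jaccard == 1) == (jac$only_a == 0 & jac$only_b == 0)))
  }

  # identical maps give Jaccard 1 everywhere; disjoint pair sets give 0
  sa <- set_from_keys(random_pair_keys(term$concepts$concept_id, 30), "NDFRT")
  ma <- abstract_to_class_pairs(sa, term)
  expect_true(all(class_pair_jaccard(ma, ma)$jaccard == 1))
})

test_that("multi-class shared counts bound the plain intersection", {
  # single class per ingredient: per-class-pair shared counts sum exactly
  # to the ATC-covered intersection; multiple classes can only inflate it
  term1 <- flat_term(n = 30, n_classes = 4, classes_per = 1, seed = 3)
  set.seed(7)
  ka <- random_pair_keys(term1$concepts$concept_id, 40)
  kb <- random_pair_keys(term1$concepts$concept_id, 40)
  sa <- set_from_keys(ka, "NDFRT"); sb <- set_from_keys(kb, "DRUGBANK")
  jac <- class_pair_jaccard(abstract_to_class_pairs(sa, term1),
                            abstract_to_class_pairs(sb, term1))
  expect_equal(sum(jac$shared), length(intersect(ka, kb)))

  term2 <- flat_term(n = 30, n_classes = 6, classes_per = 2, seed = 4)
  jac2 <- class_pair_jaccard(abstract_to_class_pairs(sa, term2),
                             abstract_to_class_pairs(sb, term2))
  expect_true(sum(jac2$shared) >= length(intersect(ka, kb)))
})
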