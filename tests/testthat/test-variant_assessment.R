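test_that("variant normalization trims padded representations", {
  k <- normalize_variant(variant_keys("1", 100, "ATT", "AT"))
  expect_equal(k$ref, "AT")
  expect_equal(k$alt, "A")
  expect_equal(k$pos, 100L)
  # already minimal: untouched
  k <- normalize_variant(variant_keys("1", 100, "CAG", "C"))
  expect_equal(unlist(k[1, ]), c(chrom = "1", pos = "100", ref = "CAG",
                                 alt = "C"))
  # prefix trimming advances pos
  k <- normalize_variant(variant_keys("2", 50, "TAG", "TAC"))
  expect_equal(k$pos, 52L)
  expect_equal(k$ref, "G")
  expect_equal(k$alt, "C")
})

test_that("normalization is idempotent on random keys", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, sample(1:5, 1), TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:5, 1), TRUE), collapse = "")
    if (ref == alt) next
    k <- variant_keys("3", sample(10:1000, 1), ref, alt)
    n1 <- normalize_variant(k)
    expect_identical(normalize_variant(n1), n1)
  }
})

test_that("reference left-alignment shifts indels in repeats and is idempotent", {
  #        123456789
  refseq <- c("7" = "GCAGAGAGT")
  # a 2 bp deletion inside the AGAGAG repeat, spelled at pos 5, should
  # left-align to the repeat's start
  k <- variant_keys("7", 5, "AGA", "A")
  n1 <- normalize_variant(k, reference = refseq)
  expect_equal(n1$pos, 2L)
  expect_equal(n1$ref, "CAG")
  expect_equal(n1$alt, "C")
  expect_identical(normalize_variant(n1, reference = refseq), n1)
  # two spellings of the same deletion meet after normalization
  k2 <- variant_keys("7", 3, "AGA", "A")
  n2 <- normalize_variant(k2, reference = refseq)
  expect_equal(n2[, c("pos", "ref", "alt")], n1[, c("pos", "ref", "alt")])
})

test_that("matching joins on normalized (patient, variant) identity", {
  key <- tiny_variant_key()
  preds <- variant_prediction_set(
    c("P001", "P001", "P002"),
    variant_keys(c("1", "1", "2"), c(150L, 500L, 600L),
                 c("A", "T", "TAA"), c("G", "C", "TTAAA")),  # padded v3
    submission_id = "9.1")
  m <- match_patient_variants(preds, key)
  expect_equal(nrow(m$tp), 2L)  # exact SNV + padded indel spelling
  expect_equal(nrow(m$fp), 1L)
  expect_equal(nrow(m$fn), 2L)
  expect_equal(nrow(m$tp) + nrow(m$fn), m$n_key)
  expect_equal(nrow(m$tp) + nrow(m$fp), m$n_predicted)
  # empty predictions: everything is a false negative
  empty <- variant_prediction_set(character(0),
                                  variant_keys(character(0), integer(0),
                                               character(0), character(0)))
  m0 <- match_patient_variants(empty, key)
  expect_equal(nrow(m0$fn), nrow(key))
  expect_equal(nrow(m0$fp), 0L)
  # predictions identical to the key: perfect downstream scores
  exact <- variant_prediction_set(key$patient_id,
                                  key[, c("chrom", "pos", "ref", "alt")])
  s <- cohort_score(match_patient_variants(exact, key))
  expect_equal(s$recall, 1)
  expect_equal(s$accuracy, 1)
})

test_that("padded spellings of random indels still match (symmetry)", {
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  for (i in 1:60) {
    anchor <- sample(bases, 1)
    ins <- paste(sample(bases, sample(1:3, 1), TRUE), collapse = "")
    pos <- sample(100:999, 1)
    key <- variant_answer_key("P1",
                              variant_keys("5", pos, anchor,
                                           paste0(anchor, ins)), "DC")
    pad <- paste(sample(bases, sample(1:3, 1), TRUE), collapse = "")
    preds <- variant_prediction_set(
      "P1", variant_keys("5", pos, paste0(anchor, pad),
                         paste0(anchor, ins, pad)))
    m <- match_patient_variants(preds, key)
    expect_equal(nrow(m$tp), 1L)
  }
})

test_that("cohort scores reproduce printed count triples at 3 decimals", {
  s <- cohort_score(list(n_correct = 178, n_predicted = 303, n_key = 217))
  expect_equal(round(s$recall, 3), 0.820)
  expect_equal(round(s$accuracy, 3), 0.587)
  s <- cohort_score(list(n_correct = 76, n_predicted = 105, n_key = 217))
  expect_equal(round(s$recall, 3), 0.350)
  expect_equal(round(s$accuracy, 3), 0.724)
  s <- cohort_score(list(n_correct = 0, n_predicted = 5, n_key = 217))
  expect_equal(s$recall, 0)
  expect_equal(s$accuracy, 0)
  # undefined, not zero, on empty denominators
  s <- cohort_score(list(n_correct = 0, n_predicted = 0, n_key = 217))
  expect_true(is.na(s$accuracy))
  expect_error(cohort_score(list(n_correct = 9, n_predicted = 3, n_key = 217)),
               "exceeds")
})

test_that("class coverage reports per-class recovery percentages", {
  key <- variant_answer_key(
    sprintf("P%02d", 1:3),
    variant_keys("1", c(101, 102, 103), c("A", "C", "G"), c("G", "T", "A")),
    c("DC", "DC", "LP"))
  preds <- variant_prediction_set("P01", variant_keys("1", 101, "A", "G"))
  cov <- class_coverage(match_patient_variants(preds, key), key)
  expect_equal(cov$coverage_percent[cov$class == "DC"], 50)
  expect_equal(cov$coverage_percent[cov$class == "LP"], 0)
  expect_true(is.na(cov$coverage_percent[cov$class == "CF"]))  # empty class
  # full recovery = 100% everywhere defined
  all_preds <- variant_prediction_set(key$patient_id,
                                      key[, c("chrom", "pos", "ref", "alt")])
  cov <- class_coverage(match_patient_variants(all_preds, key), key)
  expect_equal(cov$coverage_percent[1:2], c(NA, 100, 100)[2:3])
})

test_that("consensus histogram conserves key counts and is monotone", {
  key <- tiny_variant_key()
  cols <- c("chrom", "pos", "ref", "alt")
  p_full <- variant_prediction_set(key$patient_id, key[, cols],
                                   submission_id = "1.1")
  p_half <- variant_prediction_set(key$patient_id[1:2], key[1:2, cols],
                                   submission_id = "2.1")
  m1 <- match_patient_variants(p_full, key)
  m2 <- match_patient_variants(p_half, key)
  ch <- consensus_histogram(list(g1 = m1, g2 = m2), key)
  # each class's histogram sums to its key count
  for (cl in c("DC", "LP", "CF")) {
    expect_equal(sum(ch$histogram$count[ch$histogram$class == cl]),
                 sum(key$class == cl))
  }
  expect_equal(sort(unique(ch$per_variant$k)), c(1, 2))
  # adding a submission to a group never lowers k
  grown <- suppressMessages(group_prediction_union(list(p_half, p_full), "2"))
  m2b <- match_patient_variants(grown, key)
  ch2 <- consensus_histogram(list(g1 = m1, g2 = m2b), key)
  expect_true(all(ch2$per_variant$k >= ch$per_variant$k))
})

test_that("duplicate predicted entries cannot inflate the counts", {
  key <- tiny_variant_key()
  cols <- c("chrom", "pos", "ref", "alt")
  dup <- suppressMessages(variant_prediction_set(
    rep(key$patient_id[1], 3),
    key[c(1, 1, 1), cols]))
  expect_equal(nrow(dup), 1L)
  m <- match_patient_variants(dup, key)
  expect_equal(m$n_predicted, 1L)
  expect_equal(cohort_score(m)$accuracy, 1)
})
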