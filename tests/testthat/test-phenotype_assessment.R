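test_that("missing cells impute to zero and only to zero", {
  probs <- matrix(c(0.9, NA, NA, 0.4), 2, 2,
                  dimnames = list(c("P1", "P2"), c("ID", "ASD")))
  out <- impute_missing(phenotype_submission(probs))
  expect_equal(unname(out$probs[1, ]), c(0.9, 0))
  expect_equal(unname(out$probs[2, ]), c(0, 0.4))
  # identity on a complete table
  full <- phenotype_submission(matrix(0.5, 2, 2,
                                      dimnames = dimnames(probs)))
  expect_equal(impute_missing(full)$probs, full$probs)
})

test_that("confusion counts exclude unknown-truth patients", {
  cc <- confusion_counts(c(1, 0), c("positive", "negative"))
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 0L, fn = 0L, tn = 1L), ignore_attr = TRUE)
  cc <- confusion_counts(c(1, 1, 0), c("positive", "unknown", "negative"))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 2)
  expect_equal(cc$tp, 1)
  cc <- confusion_counts(rep(0, 5), rep("positive", 5))
  expect_equal(cc$fn, 5)
  expect_error(confusion_counts(c(2, 0), c("positive", "negative")),
               "0 and 1")
})

test_that("metric set follows the printed formulas and degenerate rules", {
  perfect <- metric_set(list(tp = 1, fp = 0, fn = 0, tn = 1))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$f1, 1)
  anti <- metric_set(list(tp = 0, fp = 1, fn = 1, tn = 0))
  expect_equal(anti$mcc, -1)
  degen <- metric_set(list(tp = 2, fp = 2, fn = 0, tn = 0))
  expect_equal(degen$mcc, 0)          # zero denominator factor
  expect_equal(degen$f1, 4 / 6)
  expect_equal(degen$acc, 0.5)
  # f1 = 0 when tp = 0 but errors exist
  expect_equal(metric_set(list(tp = 0, fp = 3, fn = 2, tn = 1))$f1, 0)
})

test_that("MCC-optimal threshold matches hand-worked cases incl. tie-break", {
  o <- optimal_mcc_threshold(c(0.2, 0.4, 0.6, 0.8),
                             truth_words(c(0, 0, 1, 1)))
  expect_equal(o$threshold, 0.5)
  expect_equal(o$mcc, 1)
  expect_equal(unname(o$binary_pred), c(0, 0, 1, 1))

  # tie between thresholds 0.4 and 0.8, broken toward the smaller
  o <- optimal_mcc_threshold(c(0.9, 0.7, 0.5, 0.3),
                             truth_words(c(1, 0, 1, 0)))
  expect_equal(o$threshold, 0.4)
  expect_equal(o$mcc, 2 / sqrt(12))

  # constant probabilities: only all-positive / all-negative available
  o <- optimal_mcc_threshold(rep(0.5, 4), truth_words(c(1, 0, 1, 0)))
  expect_equal(o$mcc, 0)

  expect_error(optimal_mcc_threshold(c(0.1, 0.9), truth_words(c(1, 1))),
               "both a positive and a negative")
})

test_that("threshold optimizer agrees with the exhaustive-sweep oracle", {
  set.seed(42)
  for (i in 1:400) {
    inst <- random_instance()
    got <- optimal_mcc_threshold(inst$probs, truth_words(inst$truth01))
    want <- mcc_threshold_oracle(inst$probs, inst$truth01)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  }
})

test_that("ROC AUC matches examples and the pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), truth_words(c(1, 1, 0, 0)))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.7, 0.5, 0.3), truth_words(c(1, 0, 1, 0)))$auc, 0.75)
  expect_equal(roc_auc(c(0.5, 0.5), truth_words(c(1, 0)))$auc, 0.5)
  set.seed(7)
  for (i in 1:400) {
    inst <- random_instance()
    expect_equal(roc_auc(inst$probs, truth_words(inst$truth01))$auc,
                 mw_auc_oracle(inst$probs, inst$truth01), tolerance = 1e-12)
  }
})

test_that("ROC curve is anchored and monotone in fpr", {
  r <- roc_auc(runif(30), truth_words(rbinom(30, 1, 0.5) + 0))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
})

test_that("ROC AUC agrees with pROC on random inputs", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:25) {
    y <- c(0, 1, rbinom(40, 1, 0.4))
    p <- sample(seq(0, 1, 0.05), 42, replace = TRUE)
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(p, truth_words(y))$auc, ref, tolerance = 1e-10)
  }
})

test_that("PR AUC follows the average-precision definition", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.3), truth_words(c(1, 1, 0))), 1)
  expect_equal(pr_auc(c(0.9, 0.7, 0.5, 0.3), truth_words(c(1, 0, 1, 0))),
               1 * (1 / 2) + (2 / 3) * (1 / 2))
  # constant scores: AP equals prevalence
  expect_equal(pr_auc(rep(0.4, 10), truth_words(c(rep(1, 3), rep(0, 7)))),
               0.3)
  expect_error(pr_auc(c(0.2, 0.4), truth_words(c(0, 0))),
               "at least one positive")
})

test_that("label swap mirrors AUC and MCC; monotone transforms are absorbed", {
  set.seed(19)
  for (i in 1:100) {
    inst <- random_instance()
    p <- inst$probs; y <- inst$truth01
    a <- roc_auc(p, truth_words(y))$auc
    expect_equal(roc_auc(p, truth_words(1 - y))$auc, 1 - a, tolerance = 1e-12)
    o <- optimal_mcc_threshold(p, truth_words(y))
    # strictly monotone transform: same AUC, same optimal MCC
    q <- plogis(5 * p - 1)
    expect_equal(roc_auc(q, truth_words(y))$auc, a, tolerance = 1e-12)
    expect_equal(optimal_mcc_threshold(q, truth_words(y))$mcc, o$mcc,
                 tolerance = 1e-12)
    # patient order invariance
    perm <- sample(length(p))
    expect_equal(roc_auc(p[perm], truth_words(y[perm]))$auc, a,
                 tolerance = 1e-12)
  }
})

test_that("per-threshold MCC negates under label swap", {
  set.seed(23)
  for (i in 1:50) {
    inst <- random_instance()
    t <- runif(1)
    pred <- as.numeric(inst$probs >= t)
    m1 <- metric_set(confusion_counts(pred, truth_words(inst$truth01)))$mcc
    m2 <- metric_set(confusion_counts(1 - pred,
                                      truth_words(inst$truth01)))$mcc
    expect_equal(m2, -m1, tolerance = 1e-12)
  }
})

test_that("bootstrap AUC is deterministic, sane, and degenerate-safe", {
  set.seed(5)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  p <- plogis(rnorm(n) + 1.2 * y)
  b1 <- bootstrap_auc(p, truth_words(y), n_iter = 300, seed = 99)
  b2 <- bootstrap_auc(p, truth_words(y), n_iter = 300, seed = 99)
  expect_identical(b1$roc_aucs, b2$roc_aucs)
  expect_identical(b1$pr_aucs, b2$pr_aucs)
  expect_length(b1$roc_aucs, 300)
  # mean bootstrap AUC close to the point estimate
  tol <- 3 * b1$sd_roc_auc / sqrt(300) + b1$sd_roc_auc
  expect_lt(abs(b1$mean_roc_auc - b1$point_roc_auc), tol)
  expect_true(b1$mean_roc_auc >= min(b1$roc_aucs) &&
              b1$mean_roc_auc <= max(b1$roc_aucs))

  # perfect separation: every resample has AUC 1
  perf <- bootstrap_auc(c(0.9, 0.8, 0.2, 0.1), truth_words(c(1, 1, 0, 0)),
                        n_iter = 50, seed = 3)
  expect_true(all(perf$roc_aucs == 1))
  expect_equal(perf$sd_roc_auc, 0)

  # one positive among many negatives: pooled resampling collapses,
  # stratified mode survives
  y2 <- c(1, rep(0, 60))
  p2 <- runif(61)
  expect_error(bootstrap_auc(p2, truth_words(y2), n_iter = 1000, seed = 1,
                             max_redraw = 5), "stratified")
  bs <- bootstrap_auc(p2, truth_words(y2), n_iter = 20, seed = 1,
                      stratified = TRUE)
  expect_length(bs$roc_aucs, 20)
})

test_that("assess_phenotypes produces coherent per-trait metrics", {
  cohort <- tiny_cohort()
  truth <- tiny_truth(cohort)
  set.seed(31)
  subs <- list(
    "1.1" = simulate_phenotype_submission(
      truth, skill_profile(0.9, miss_rate = 0, traits = cohort$trait_names),
      seed = 1, submission_id = "1.1"),
    "2.1" = simulate_phenotype_submission(
      truth, skill_profile(0.6, miss_rate = 0.1,
                           traits = cohort$trait_names),
      seed = 2, submission_id = "2.1"))
  res <- assess_phenotypes(subs, truth, n_boot = 25, seed = 7)
  m <- res$metrics
  expect_equal(nrow(m), 4L)
  expect_true(all(m$mcc >= -1 & m$mcc <= 1))
  expect_true(all(m$auc_point >= 0 & m$auc_point <= 1))
  # confusion totals equal known-label counts per trait
  known <- colSums(unclass(truth) != "unknown")
  expect_equal(m$tp + m$fp + m$fn + m$tn, unname(known[m$trait]))
  # reported MCC equals metric_set at the reported binarization
  for (i in seq_len(nrow(m))) {
    cc <- confusion_counts(res$binarized[[m$submission_id[i]]][, m$trait[i]],
                           unclass(truth)[, m$trait[i]])
    expect_equal(metric_set(cc)$mcc, m$mcc[i])
  }
  # master-seed stability: same seed reproduces bootstrap means exactly
  res2 <- assess_phenotypes(subs, truth, n_boot = 25, seed = 7)
  expect_identical(res$metrics$auc_boot_mean, res2$metrics$auc_boot_mean)
  # adding a submission leaves the first one's bootstrap untouched
  res3 <- assess_phenotypes(c(subs, list("3.1" = subs[["1.1"]])), truth,
                            n_boot = 25, seed = 7)
  expect_identical(res3$metrics$auc_boot_mean[1:4],
                   res$metrics$auc_boot_mean)
})
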