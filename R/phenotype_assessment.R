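## Phenotype track scoring: imputation, MCC-optimal binarization, confusion
## metrics, ROC/PR curves and bootstrap AUC.

# Truth labels -> 1 / 0 / NA (unknown).
truth01 <- function(truth) {
  if (is.numeric(truth)) return(ifelse(is.na(truth), NA_real_, truth))
  t <- tolower(as.character(truth))
  ok <- t %in% c("positive", "negative", "unknown")
  if (!all(ok))
    stopf("truth labels must be positive/negative/unknown; saw: %s",
          paste(unique(t[!ok]), collapse = ", "))
  ifelse(t == "positive", 1, ifelse(t == "negative", 0, NA_real_))
}

#' Impute missing submission probabilities as zero
#'
#' The assessment rule for cells the predictor left blank (`"*"` on the
#' template): a missing prediction is scored as probability zero.  Imputation
#' is deliberately deferred to this step so the parsed file stays auditable.
#'
#' @param sub A `phenotype_submission`.
#' @return The submission with every missing cell set to `0.0`.
#' @export
impute_missing <- function(sub) {
  sub$probs[is.na(sub$probs)] <- 0
  sub
}

#' Confusion counts of a binary prediction against tri-state truth
#'
#' Patients whose truth label is unknown are excluded from all four counts;
#' `tp + fp + fn + tn` therefore equals the number of patients with a known
#' label.
#'
#' @param binary_pred Numeric/integer vector of 0/1 predictions, one per
#'   patient.
#' @param truth Tri-state labels (`positive`/`negative`/`unknown`) or a
#'   numeric 1/0/`NA` vector of the same length.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_counts <- function(binary_pred, truth) {
  if (length(binary_pred) != length(truth))
    stopf("prediction and truth lengths differ (%d vs %d)",
          length(binary_pred), length(truth))
  if (!all(binary_pred %in% c(0, 1)))
    stopf("binary_pred must contain only 0 and 1")
  t <- truth01(truth)
  known <- !is.na(t)
  p <- binary_pred[known]; t <- t[known]
  structure(list(tp = sum(p == 1 & t == 1),
                 fp = sum(p == 1 & t == 0),
                 fn = sum(p == 0 & t == 1),
                 tn = sum(p == 0 & t == 0)),
            class = "confusion_counts")
}

mcc_from_counts <- function(tp, fp, fn, tn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)   # zero-factor convention: MCC defined as 0
  (tp * tn - fp * fn) / sqrt(den)
}

#' Derived metrics of a confusion-count object
#'
#' Matthews correlation coefficient, accuracy, F1, sensitivity and
#' specificity.  Conventions for degenerate denominators: MCC is 0 whenever
#' any factor of its denominator is 0; sensitivity, specificity and F1 are 0
#' when their denominator is 0.
#'
#' @param cc A `confusion_counts` object (or list with `tp`, `fp`, `fn`,
#'   `tn`).
#' @return Object of class `metric_set`: list with `mcc`, `acc`, `f1`,
#'   `sensitivity`, `specificity`.
#' @export
metric_set <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; fn <- cc$fn; tn <- cc$tn
  n <- tp + fp + fn + tn
  ratio0 <- function(num, den) if (den == 0) 0 else num / den
  structure(list(mcc = mcc_from_counts(tp, fp, fn, tn),
                 acc = ratio0(tp + tn, n),
                 f1 = ratio0(2 * tp, 2 * tp + fp + fn),
                 sensitivity = ratio0(tp, tp + fn),
                 specificity = ratio0(tn, tn + fp)),
            class = "metric_set")
}

# Cumulative confusion counts along the descending-score sweep, collapsed to
# tie blocks.  Returns per-block tp/fp after predicting the block (and all
# higher scores) positive, plus the block's score values.
sweep_blocks <- function(probs, t) {
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]; y <- t[ord]
  last <- which(!duplicated(p, fromLast = TRUE))  # last index of each block
  list(values = p[last],
       tp = cumsum(y)[last],
       fp = cumsum(1 - y)[last],
       P = sum(y), N = sum(1 - y))
}

#' MCC-optimal binarization threshold
#'
#' Sweeps candidate thresholds — the midpoints between consecutive distinct
#' probabilities plus sentinels below the minimum and above the maximum — and
#' returns the threshold maximizing the MCC of the rule `p >= threshold -> 1`.
#' Ties are broken toward the smallest threshold (the more sensitive operating
#' point).  Patients with unknown truth are ignored for optimization but still
#' receive a binarized prediction.
#'
#' @param probs Numeric vector of probabilities (post-imputation).
#' @param truth Tri-state truth labels, same length.
#' @return List with `threshold`, `mcc` (at the threshold) and `binary_pred`
#'   (0/1 vector over all patients, named like `probs`).
#' @export
optimal_mcc_threshold <- function(probs, truth) {
  t <- truth01(truth)
  known <- !is.na(t)
  if (sum(t[known] == 1) == 0 || sum(t[known] == 0) == 0)
    stopf("optimal_mcc_threshold needs both a positive and a negative label")
  b <- sweep_blocks(probs[known], t[known])
  v <- b$values                       # descending distinct values
  nb <- length(v)
  # Cut k = predict blocks 1..k positive; k = 0 none, k = nb all.
  # Threshold for cut k: midpoint of v[k] and v[k+1]; sentinels outside range.
  thr <- c(v[1] + 1, if (nb > 1) (v[-nb] + v[-1]) / 2, v[nb] - 1)
  tp <- c(0, b$tp); fp <- c(0, b$fp)
  mcc <- vapply(seq_along(thr), function(i)
    mcc_from_counts(tp[i], fp[i], b$P - tp[i], b$N - fp[i]), numeric(1))
  best <- max(mcc)
  # ties -> smallest threshold = largest cut index
  i <- max(which(mcc == best))
  pred <- as.numeric(probs >= thr[i])
  names(pred) <- names(probs)
  list(threshold = thr[i], mcc = best, binary_pred = pred)
}

#' ROC curve and area under it
#'
#' Threshold-sweep ROC with tied scores collapsed into single curve points and
#' trapezoidal area; numerically identical to the Mann-Whitney U statistic
#' with ties counted one half.  Unknown truth labels are excluded.
#'
#' @inheritParams optimal_mcc_threshold
#' @return Object of class `roc_result`: list with `points` (data frame
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(probs, truth) {
  t <- truth01(truth)
  known <- !is.na(t)
  t <- t[known]; p <- probs[known]
  if (sum(t == 1) == 0 || sum(t == 0) == 0)
    stopf("roc_auc needs both a positive and a negative label")
  b <- sweep_blocks(p, t)
  fpr <- c(0, b$fp / b$N)
  tpr <- c(0, b$tp / b$P)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d curve points)\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

#' Precision-recall AUC (average precision)
#'
#' Average-precision summation: AP = sum over descending-threshold tie blocks
#' of (recall increment) x (precision at the block).  No linear interpolation
#' of precision is applied.  Unknown truth labels are excluded.
#'
#' @inheritParams optimal_mcc_threshold
#' @return Single numeric value in `[0, 1]`.
#' @export
pr_auc <- function(probs, truth) {
  t <- truth01(truth)
  known <- !is.na(t)
  t <- t[known]; p <- probs[known]
  if (sum(t == 1) == 0)
    stopf("pr_auc needs at least one positive label")
  b <- sweep_blocks(p, t)
  recall <- b$tp / b$P
  precision <- b$tp / (b$tp + b$fp)
  sum(diff(c(0, recall)) * precision)
}

#' Bootstrap distribution of ROC and PR AUC
#'
#' Resamples the known-label patients with replacement (same size) `n_iter`
#' times and computes both AUCs per resample.  A resample containing a single
#' truth class is discarded and redrawn, up to `max_redraw` consecutive
#' attempts; persistent degeneracy (a pathologically small class) raises an
#' error suggesting the stratified mode.  With `stratified = TRUE` positives
#' and negatives are resampled separately, preserving class counts.
#'
#' @inheritParams optimal_mcc_threshold
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Integer seed; identical seeds give identical AUC lists.
#' @param stratified Resample within classes instead of the pooled cohort.
#' @param max_redraw Redraw cap per iteration for degenerate resamples.
#' @return Object of class `bootstrap_auc`: `n_iter`, `seed`, `roc_aucs`,
#'   `pr_aucs`, `mean_roc_auc`, `sd_roc_auc`, `mean_pr_auc`, plus the point
#'   estimates `point_roc_auc`, `point_pr_auc` on the full data.
#' @export
bootstrap_auc <- function(probs, truth, n_iter = 1000, seed = NULL,
                          stratified = FALSE, max_redraw = 100) {
  t <- truth01(truth)
  known <- which(!is.na(t))
  p <- probs[known]; y <- t[known]
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg))
    stopf("bootstrap_auc needs both a positive and a negative label")
  n <- length(y)
  roc <- numeric(n_iter); pr <- numeric(n_iter)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      if (stratified) {
        idx <- c(sample(pos, length(pos), replace = TRUE),
                 sample(neg, length(neg), replace = TRUE))
      } else {
        redraw <- 0L
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(y[idx])) == 2L) break
          redraw <- redraw + 1L
          if (redraw >= max_redraw)
            stopf(paste("bootstrap resamples keep collapsing to one class;",
                        "use stratified = TRUE for this trait"))
        }
      }
      roc[i] <- roc_auc(p[idx], y[idx])$auc
      pr[i] <- pr_auc(p[idx], y[idx])
    }
  })
  structure(list(n_iter = n_iter, seed = seed,
                 roc_aucs = roc, pr_aucs = pr,
                 mean_roc_auc = mean(roc), sd_roc_auc = stats::sd(roc),
                 mean_pr_auc = mean(pr),
                 point_roc_auc = roc_auc(p, y)$auc,
                 point_pr_auc = pr_auc(p, y)),
            class = "bootstrap_auc")
}

#' @export
print.bootstrap_auc <- function(x, ...) {
  cat(sprintf("<bootstrap_auc> %d iterations: ROC AUC %.4f +/- %.4f (point %.4f)\n",
              x$n_iter, x$mean_roc_auc, x$sd_roc_auc, x$point_roc_auc))
  invisible(x)
}

#' Assess phenotype submissions against the answer key
#'
#' Full phenotype-track pipeline, per submission and trait: impute missing
#' cells as zero, find the MCC-optimal threshold, compute confusion metrics at
#' that threshold, and estimate ROC/PR AUC with a patient bootstrap.  Each
#' (submission, trait) bootstrap runs on its own seed derived from the master
#' seed by stable hashing, so adding a submission never perturbs the others'
#' random streams.
#'
#' @param submissions List of `phenotype_submission` objects.
#' @param truth A `phenotype_answer_key` over the same patients and traits.
#' @param n_boot Bootstrap iterations per (submission, trait).
#' @param seed Master seed.
#' @param unknown_as_negative Treat unknown truth labels as negative instead
#'   of excluding them (the stricter reading).
#' @param stratified Passed to [bootstrap_auc()].
#' @return Object of class `phenotype_assessment`: `metrics` (data frame with
#'   one row per submission x trait: threshold, confusion counts, MCC, ACC,
#'   F1, sensitivity, specificity, point and bootstrap AUCs), `binarized`
#'   (list of 0/1 matrices at the optimal thresholds), `bootstrap` (nested
#'   list of `bootstrap_auc` objects), and `traits`.
#' @export
assess_phenotypes <- function(submissions, truth, n_boot = 1000, seed = 1,
                              unknown_as_negative = FALSE,
                              stratified = FALSE) {
  if (is.null(names(submissions)) || any(!nzchar(names(submissions))))
    names(submissions) <- vapply(submissions, `[[`, "", "submission_id")
  traits <- colnames(truth)
  lab <- unclass(truth)
  if (unknown_as_negative) lab[lab == "unknown"] <- "negative"
  rows <- list(); boots <- list(); binarized <- list()
  for (sid in names(submissions)) {
    sub <- impute_missing(submissions[[sid]])
    if (!identical(rownames(sub$probs), rownames(lab)))
      stopf("submission %s: patient rows do not match the answer key", sid)
    bin <- matrix(NA_real_, nrow(lab), length(traits),
                  dimnames = list(rownames(lab), traits))
    boots[[sid]] <- list()
    for (tr in traits) {
      p <- sub$probs[, tr]; y <- lab[, tr]
      opt <- optimal_mcc_threshold(p, y)
      bin[, tr] <- opt$binary_pred
      ms <- metric_set(confusion_counts(opt$binary_pred, y))
      bt <- bootstrap_auc(p, y, n_iter = n_boot,
                          seed = derive_seed(seed, sid, tr),
                          stratified = stratified)
      boots[[sid]][[tr]] <- bt
      cc <- confusion_counts(opt$binary_pred, y)
      rows[[length(rows) + 1L]] <- data.frame(
        submission_id = sid, group_id = sub$group_id, trait = tr,
        threshold = opt$threshold,
        tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
        mcc = ms$mcc, acc = ms$acc, f1 = ms$f1,
        sensitivity = ms$sensitivity, specificity = ms$specificity,
        auc_point = bt$point_roc_auc,
        auc_boot_mean = bt$mean_roc_auc, auc_boot_sd = bt$sd_roc_auc,
        pr_auc_point = bt$point_pr_auc, pr_auc_boot_mean = bt$mean_pr_auc,
        stringsAsFactors = FALSE)
    }
    binarized[[sid]] <- bin
  }
  structure(list(metrics = do.call(rbind, rows), binarized = binarized,
                 bootstrap = boots, traits = traits),
            class = "phenotype_assessment")
}

#' @export
print.phenotype_assessment <- function(x, ...) {
  cat(sprintf("<phenotype_assessment> %d submissions x %d traits\n",
              length(x$binarized), length(x$traits)))
  invisible(x)
}

#' Submission x trait AUC matrix of an assessment
#'
#' @param assessment A `phenotype_assessment`.
#' @param type `"boot_mean"` (mean bootstrap ROC AUC, the ranking input) or
#'   `"point"` (single-pass ROC AUC).
#' @return Numeric matrix, submissions in rows, traits in columns.
#' @export
auc_matrix <- function(assessment, type = c("boot_mean", "point")) {
  type <- match.arg(type)
  col <- if (type == "boot_mean") "auc_boot_mean" else "auc_point"
  m <- assessment$metrics
  subs <- unique(m$submission_id)
  out <- matrix(NA_real_, length(subs), length(assessment$traits),
                dimnames = list(subs, assessment$traits))
  out[cbind(match(m$submission_id, subs), match(m$trait, assessment$traits))] <-
    m[[col]]
  out
}
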