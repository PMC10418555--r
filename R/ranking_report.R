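## Cross-submission standardization and ranking, diagnosed-subset re-analysis
## and phenotype group-consensus counts.

#' Per-trait z-scores and overall ranking of submissions
#'
#' Standardizes each trait's AUC column across submissions
#' (`z = (a - mean) / sd`, sample SD) so traits of different difficulty
#' contribute comparably, then ranks submissions by the unweighted mean z
#' over traits (rank 1 = best; ties broken by submission id).  A constant
#' column (SD 0) maps to all-zero z.
#'
#' @param auc Numeric matrix submissions x traits (e.g. from
#'   [auc_matrix()]), rownames = submission ids.
#' @return Object of class `zscore_table`: `z` (matrix), `mean_z` (named
#'   vector), `rank` (named integer vector, a permutation of
#'   `1..n_submissions`).
#' @export
zscore_by_trait <- function(auc) {
  auc <- as.matrix(auc)
  if (is.null(rownames(auc))) rownames(auc) <- seq_len(nrow(auc))
  if (nrow(auc) < 2L)
    warning("single submission: all z-scores are 0, rank 1")
  z <- apply(auc, 2L, function(col) {
    s <- stats::sd(col)
    if (nrow(auc) < 2L || is.na(s) || s == 0) rep(0, length(col))
    else (col - mean(col)) / s
  })
  z <- matrix(z, nrow = nrow(auc), dimnames = dimnames(auc))
  mean_z <- rowMeans(z)
  ord <- order(-mean_z, rownames(auc))
  rank <- integer(nrow(auc)); rank[ord] <- seq_len(nrow(auc))
  names(rank) <- rownames(auc)
  structure(list(z = z, mean_z = mean_z, rank = rank),
            class = "zscore_table")
}

#' @export
print.zscore_table <- function(x, ...) {
  cat(sprintf("<zscore_table> %d submissions x %d traits; best: %s (mean z %.2f)\n",
              nrow(x$z), ncol(x$z), names(which(x$rank == 1L)),
              max(x$mean_z)))
  invisible(x)
}

#' Format a z-score table as a leaderboard data frame
#'
#' One row per submission: the per-trait z values, the mean z and the rank,
#' ordered by rank.
#' @param zt A `zscore_table`.
#' @return Data frame.
#' @export
zscore_leaderboard <- function(zt) {
  df <- data.frame(submission_id = rownames(zt$z),
                   round(zt$z, 4), mean_z = round(zt$mean_z, 4),
                   rank = zt$rank, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- df[order(df$rank), ]
  rownames(df) <- NULL
  df
}

#' Patients with a molecular diagnosis in the answer key
#'
#' The diagnosed subset: patients for whom the laboratory identified at least
#' one classified variant (any of DC/LP/CF).
#'
#' @param key A `variant_answer_key`.
#' @return Character vector of patient ids (in cohort order when `cohort` is
#'   given).
#' @param cohort Optional `cohort_definition` used to order the result.
#' @export
diagnosed_subset <- function(key, cohort = NULL) {
  ids <- unique(key$patient_id)
  if (!is.null(cohort)) ids <- cohort$patient_ids[cohort$patient_ids %in% ids]
  ids
}

#' Re-run the phenotype assessment on a patient subset
#'
#' Restricts the answer key and every submission to the given patients
#' (typically the diagnosed subset) and reruns the identical pipeline —
#' thresholds are re-optimized on the subset.  Traits left with a single
#' truth class after restriction are dropped with a warning and excluded
#' from the mean-z ranking.
#'
#' @param submissions List of `phenotype_submission` objects.
#' @param truth A `phenotype_answer_key`.
#' @param subset Character vector of patient ids to keep.
#' @inheritParams assess_phenotypes
#' @return List: `assessment` (a `phenotype_assessment` on the subset),
#'   `zscores` (a `zscore_table` on its mean bootstrap AUCs), and
#'   `dropped_traits`.
#' @export
rerun_on_subset <- function(submissions, truth, subset, n_boot = 1000,
                            seed = 1, unknown_as_negative = FALSE,
                            stratified = FALSE) {
  subset <- as.character(subset)
  if (!length(subset)) stopf("empty patient subset")
  missing <- setdiff(subset, rownames(truth))
  if (length(missing))
    stopf("subset patient(s) not in answer key: %s",
          paste(missing, collapse = ", "))
  keep <- rownames(truth) %in% subset
  lab <- unclass(truth)[keep, , drop = FALSE]
  ok_trait <- vapply(colnames(lab), function(tr) {
    t <- truth01(lab[, tr])
    sum(t == 1, na.rm = TRUE) > 0 && sum(t == 0, na.rm = TRUE) > 0
  }, logical(1))
  dropped <- colnames(lab)[!ok_trait]
  if (length(dropped))
    warning(sprintf("trait(s) single-class on the subset, dropped: %s",
                    paste(dropped, collapse = ", ")))
  lab <- lab[, ok_trait, drop = FALSE]
  subs <- lapply(submissions, function(s) {
    s$probs <- s$probs[keep, colnames(lab), drop = FALSE]
    s
  })
  assessment <- assess_phenotypes(subs, phenotype_answer_key(lab),
                                  n_boot = n_boot, seed = seed,
                                  unknown_as_negative = unknown_as_negative,
                                  stratified = stratified)
  list(assessment = assessment,
       zscores = zscore_by_trait(auc_matrix(assessment)),
       dropped_traits = dropped)
}

#' Group-consensus counts for truth-positive patients
#'
#' For each trait and each truth-positive patient, counts the number of
#' groups that predicted the trait (a group counts as correct if at least one
#' of its submissions predicts positive at its MCC-optimal threshold; set
#' `strict = TRUE` to require every submission of the group).  Truth-negative
#' and unknown patients are excluded.  The per-trait histogram over
#' `0..n_groups` sums to the trait's positive-patient count.
#'
#' @param binarized_by_group Named list with one 0/1 matrix
#'   (patients x traits) per group — each group's submissions already
#'   combined; see [group_binarized()].
#' @param truth A `phenotype_answer_key`.
#' @return Object of class `group_consensus`: `per_patient` (data frame
#'   `trait`, `patient_id`, `n_groups_correct`) and `histogram` (data frame
#'   `trait`, `k`, `count`).
#' @export
group_consensus <- function(binarized_by_group, truth) {
  traits <- colnames(truth)
  n_groups <- length(binarized_by_group)
  pp <- list(); hist <- list()
  for (tr in traits) {
    pos <- rownames(truth)[unclass(truth)[, tr] == "positive"]
    k <- integer(length(pos)); names(k) <- pos
    for (g in binarized_by_group)
      k <- k + as.integer(g[pos, tr] == 1)
    pp[[tr]] <- data.frame(trait = tr, patient_id = pos,
                           n_groups_correct = unname(k),
                           stringsAsFactors = FALSE)
    hist[[tr]] <- data.frame(trait = tr, k = 0:n_groups,
                             count = vapply(0:n_groups,
                                            function(i) sum(k == i),
                                            integer(1)))
  }
  structure(list(per_patient = do.call(rbind, c(pp, make.row.names = FALSE)),
                 histogram = do.call(rbind, c(hist, make.row.names = FALSE)),
                 n_groups = n_groups),
            class = "group_consensus")
}

#' Combine a group's binarized submissions
#'
#' Builds per-group 0/1 matrices from an assessment's binarized predictions:
#' under `mode = "any"` a group predicts positive where at least one of its
#' submissions does; `mode = "all"` is the strict variant.
#'
#' @param assessment A `phenotype_assessment`.
#' @param groups Named list mapping group id -> character vector of its
#'   submission ids; defaults to grouping by [submission_group()] of the
#'   submission ids.
#' @param mode `"any"` or `"all"`.
#' @return Named list of 0/1 matrices, one per group.
#' @export
group_binarized <- function(assessment, groups = NULL,
                            mode = c("any", "all")) {
  mode <- match.arg(mode)
  sids <- names(assessment$binarized)
  if (is.null(groups)) groups <- split(sids, submission_group(sids))
  lapply(groups, function(members) {
    mats <- assessment$binarized[members]
    agg <- Reduce(`+`, mats)
    if (mode == "any") (agg > 0) + 0 else (agg == length(mats)) + 0
  })
}
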