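## Variant track: representation normalization, patient-specific matching
## against the classified answer key, cohort scores, class coverage and
## cross-group consensus.

#' Normalize variant representations
#'
#' Reduces each key to a minimal representation so that differently padded
#' spellings of the same indel match: the common allele suffix is trimmed,
#' then the common prefix (always keeping at least one base on each side and
#' adjusting `pos` for trimmed prefix bases).  When a reference sequence is
#' supplied, indels are additionally left-aligned against it before prefix
#' trimming.  The operation is idempotent.
#'
#' @param keys Data frame of variant keys (columns `chrom`, `pos`, `ref`,
#'   `alt`; extra columns are carried through).
#' @param reference Optional named character vector (or list) of chromosome
#'   sequences, names without the "chr" prefix, for left alignment.
#' @return The data frame with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(keys, reference = NULL) {
  if (!nrow(keys)) return(keys)
  for (i in seq_len(nrow(keys))) {
    pos <- keys$pos[i]
    ref <- strsplit(keys$ref[i], "")[[1]]
    alt <- strsplit(keys$alt[i], "")[[1]]
    if (!length(ref) || !length(alt))
      stopf("empty allele in variant at %s:%d", keys$chrom[i], pos)
    # 1) trim shared suffix, keeping >= 1 base each side
    while (length(ref) > 1L && length(alt) > 1L &&
           ref[length(ref)] == alt[length(alt)]) {
      ref <- ref[-length(ref)]; alt <- alt[-length(alt)]
    }
    # 2) left-align indels against the reference, if available
    if (!is.null(reference)) {
      seq <- reference[[normalize_chrom(keys$chrom[i])]]
      if (!is.null(seq)) {
        chars <- strsplit(toupper(seq), "")[[1]]
        while (length(ref) != length(alt) && pos > 1L &&
               ref[length(ref)] == alt[length(alt)]) {
          prev <- chars[pos - 1L]
          if (is.na(prev)) break
          ref <- c(prev, ref[-length(ref)])
          alt <- c(prev, alt[-length(alt)])
          pos <- pos - 1L
        }
      }
    }
    # 3) trim shared prefix, keeping >= 1 base each side
    while (length(ref) > 1L && length(alt) > 1L && ref[1L] == alt[1L]) {
      ref <- ref[-1L]; alt <- alt[-1L]; pos <- pos + 1L
    }
    keys$pos[i] <- pos
    keys$ref[i] <- paste(ref, collapse = "")
    keys$alt[i] <- paste(alt, collapse = "")
  }
  keys
}

#' Match predicted variants against the answer key
#'
#' A predicted (patient, variant) pair is a true positive iff the same pair —
#' after normalization on both sides — appears in the answer key; predicted
#' class labels, if any, are ignored for matching.  Unmatched key entries are
#' false negatives, unmatched predictions false positives.  True negatives
#' are not evaluated (predictors only output variants they do assign).
#'
#' @param preds A `variant_prediction_set` (already deduplicated by
#'   construction).
#' @param key A `variant_answer_key`.
#' @param reference Optional reference sequences for left alignment, see
#'   [normalize_variant()].
#' @return Object of class `match_result`: data frames `tp` (with the key's
#'   class column), `fp`, `fn`, plus `n_predicted` and `n_key`.
#' @export
match_patient_variants <- function(preds, key, reference = NULL) {
  kn <- normalize_variant(as.data.frame(key), reference)
  pn <- normalize_variant(as.data.frame(preds), reference)
  pn <- pn[!duplicated(variant_id(pn)), , drop = FALSE]
  kid <- variant_id(kn); pid <- variant_id(pn)
  hit <- kid %in% pid
  cols <- c("patient_id", "chrom", "pos", "ref", "alt")
  structure(list(tp = kn[hit, c(cols, "class"), drop = FALSE],
                 fn = kn[!hit, c(cols, "class"), drop = FALSE],
                 fp = pn[!(pid %in% kid), cols, drop = FALSE],
                 n_predicted = nrow(pn), n_key = nrow(kn),
                 submission_id = attr(preds, "submission_id") %||% NA_character_,
                 group_id = attr(preds, "group_id") %||% NA_character_),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result %s> TP %d / FP %d / FN %d (key %d, predicted %d)\n",
              x$submission_id, nrow(x$tp), nrow(x$fp), nrow(x$fn),
              x$n_key, x$n_predicted))
  invisible(x)
}

#' Cohort-level recall and accuracy of a variant match
#'
#' Recall is correctly predicted variants over all answer-key variants;
#' "accuracy", keeping the challenge's terminology, is correctly predicted
#' variants over all predicted variants (precision under standard naming).
#' A zero denominator leaves the metric `NA` (undefined), never 0.
#'
#' @param match A `match_result`, or a list/data frame supplying `n_correct`,
#'   `n_predicted`, `n_key` directly (so printed count triples can be scored
#'   as-is).
#' @return Object of class `cohort_variant_score`: `n_correct`,
#'   `n_predicted`, `n_key`, `recall`, `accuracy`.
#' @export
cohort_score <- function(match) {
  if (inherits(match, "match_result")) {
    n_correct <- nrow(match$tp); n_predicted <- match$n_predicted
    n_key <- match$n_key
  } else {
    n_correct <- match$n_correct; n_predicted <- match$n_predicted
    n_key <- match$n_key
  }
  if (n_correct > min(n_predicted, n_key))
    stopf("n_correct (%d) exceeds min(n_predicted, n_key)", n_correct)
  structure(list(n_correct = n_correct, n_predicted = n_predicted,
                 n_key = n_key,
                 recall = if (n_key > 0) n_correct / n_key else NA_real_,
                 accuracy = if (n_predicted > 0) n_correct / n_predicted
                            else NA_real_),
            class = "cohort_variant_score")
}

#' @export
print.cohort_variant_score <- function(x, ...) {
  cat(sprintf("<cohort_variant_score> %d/%d key (recall %.3f), %d predicted (accuracy %.3f)\n",
              x$n_correct, x$n_key, x$recall, x$n_predicted, x$accuracy))
  invisible(x)
}

#' Per-class coverage of the answer key
#'
#' For each variant class (DC disease causing, LP likely pathogenic /
#' putative, CF contributing factor): how many key entries the submission
#' recovered, as a percentage of the class's key entries.  A class absent
#' from the key has undefined (`NA`) coverage.
#'
#' @param match A `match_result`.
#' @param key The `variant_answer_key` the match was computed against.
#' @return Data frame of class `class_coverage` with one row per class:
#'   `class`, `n_key`, `n_correct`, `coverage_percent`.
#' @export
class_coverage <- function(match, key) {
  out <- data.frame(class = VARIANT_CLASSES,
                    n_key = NA_integer_, n_correct = NA_integer_,
                    coverage_percent = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(VARIANT_CLASSES)) {
    cl <- VARIANT_CLASSES[i]
    nk <- sum(key$class == cl)
    nc <- sum(match$tp$class == cl)
    out$n_key[i] <- nk
    out$n_correct[i] <- nc
    out$coverage_percent[i] <- if (nk > 0) 100 * nc / nk else NA_real_
  }
  structure(out, class = c("class_coverage", "data.frame"))
}

#' Cross-group consensus over answer-key variants
#'
#' For every answer-key entry, counts the number of distinct groups whose
#' (union-of-submissions) predictions recovered it, then tabulates a
#' histogram of that count per variant class.  The histogram of a class sums
#' to the class's key count.
#'
#' @param per_group_matches Named list with one `match_result` per group; a
#'   group's predictions should already be the union over its submissions
#'   (see [group_prediction_union()]).
#' @param key The `variant_answer_key`.
#' @return Object of class `consensus_histogram`: `per_variant` (key entries
#'   with a column `k`, the number of groups recovering each) and `histogram`
#'   (data frame `class`, `k`, `count` over `k = 0..n_groups`).
#' @export
consensus_histogram <- function(per_group_matches, key) {
  kid <- variant_id(key)
  k <- integer(length(kid))
  for (m in per_group_matches)
    k <- k + as.integer(kid %in% variant_id(m$tp))
  per_variant <- cbind(as.data.frame(key), k = k)
  n_groups <- length(per_group_matches)
  hist <- expand.grid(class = VARIANT_CLASSES, k = 0:n_groups,
                      stringsAsFactors = FALSE)
  hist$count <- mapply(function(cl, kk) sum(key$class == cl & k == kk),
                       hist$class, hist$k)
  hist <- hist[order(hist$class, hist$k), ]
  rownames(hist) <- NULL
  structure(list(per_variant = per_variant, histogram = hist,
                 n_groups = n_groups),
            class = "consensus_histogram")
}

#' Union of a group's prediction sets
#'
#' Pools the (patient, variant) entries of several submissions of one group
#' into a single deduplicated prediction set — the granularity at which
#' group-level consensus is assessed.
#'
#' @param preds List of `variant_prediction_set` objects of one group.
#' @param group_id Group identifier for the result.
#' @return A `variant_prediction_set`.
#' @export
group_prediction_union <- function(preds, group_id = NULL) {
  group_id <- group_id %||% attr(preds[[1]], "group_id") %||% "group"
  df <- do.call(rbind, lapply(preds, as.data.frame))
  variant_prediction_set(df$patient_id,
                         df[, c("chrom", "pos", "ref", "alt")],
                         score = df$score,
                         submission_id = paste0(group_id, ".union"),
                         group_id = group_id)
}
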