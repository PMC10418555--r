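# Independent oracles and tiny fixture builders used across the suite.
# The oracles deliberately share no code with the package implementation.

# Mann-Whitney pair-counting AUC: concordant pairs + half the tied pairs.
mw_auc_oracle <- function(probs, truth01) {
  pos <- probs[truth01 == 1]
  neg <- probs[truth01 == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

mcc_oracle <- function(tp, fp, fn, tn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# Exhaustive sweep over the candidate threshold set (midpoints + sentinels),
# rule p >= t, ties broken toward the smallest threshold.
mcc_threshold_oracle <- function(probs, truth01) {
  v <- sort(unique(probs))
  cands <- c(min(v) - 1, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2,
             max(v) + 1)
  best <- list(threshold = NA_real_, mcc = -Inf)
  for (t in cands) {
    pred <- as.numeric(probs >= t)
    tp <- sum(pred == 1 & truth01 == 1); fp <- sum(pred == 1 & truth01 == 0)
    fn <- sum(pred == 0 & truth01 == 1); tn <- sum(pred == 0 & truth01 == 0)
    m <- mcc_oracle(tp, fp, fn, tn)
    if (m > best$mcc || (m == best$mcc && t < best$threshold))
      best <- list(threshold = t, mcc = m)
  }
  best
}

# Random small scoring instance with both classes present; probabilities drawn
# from a coarse grid so ties are frequent.
random_instance <- function(n_max = 12) {
  n <- sample(2:n_max, 1)
  repeat {
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) == 2) break
  }
  list(probs = sample(seq(0, 1, by = 0.1), n, replace = TRUE),
       truth01 = y)
}

truth_words <- function(truth01) {
  ifelse(is.na(truth01), "unknown", ifelse(truth01 == 1, "positive", "negative"))
}

# A small 8-patient cohort with a fully known two-trait answer key.
tiny_cohort <- function() {
  regions <- data.frame(chrom = c("1", "2"), start = c(100L, 500L),
                        end = c(1100L, 1500L), gene = c("GA", "GB"))
  cohort_definition(sprintf("P%03d", 1:8), c("ID", "ASD"), regions)
}

tiny_truth <- function(cohort = tiny_cohort()) {
  labels <- matrix("negative", length(cohort$patient_ids),
                   length(cohort$trait_names),
                   dimnames = list(cohort$patient_ids, cohort$trait_names))
  labels[1:4, "ID"] <- "positive"
  labels[c(1, 5), "ASD"] <- "positive"
  labels[8, "ASD"] <- "unknown"
  phenotype_answer_key(labels)
}

tiny_variant_key <- function() {
  variant_answer_key(
    c("P001", "P001", "P002", "P003"),
    variant_keys(c("1", "1", "2", "2"), c(150L, 300L, 600L, 700L),
                 c("A", "CAG", "T", "G"), c("G", "C", "TTA", "A")),
    c("DC", "LP", "CF", "DC"))
}
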