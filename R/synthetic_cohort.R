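## Synthetic cohort, answer keys, panel VCFs and submissions with the
## statistical structure the assessment assumes, so the full pipeline runs
## without access to the (unreleased) patient data.

#' Toy 74-gene panel regions
#'
#' A synthetic stand-in for the challenge's captured-region BED: one 2 kb
#' half-open 0-based interval per gene, 74 genes spread over chromosomes
#' 1-22 and X with hg19-style names (no "chr" prefix).  Gene symbols are
#' synthetic (`PANELG01` ...); no real reference coordinates are implied.
#'
#' @return Data frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
default_gene_regions <- function() {
  n <- 74L
  chrom <- c(rep(as.character(1:22), each = 3L), rep("X", 8L))[seq_len(n)]
  within_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- as.integer(1e6 + (within_chrom - 1L) * 1e5)
  data.frame(chrom = chrom, start = start, end = start + 2000L,
             gene = sprintf("PANELG%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the challenge cohort's marginal structure: 415
#' patients; per-trait positive counts ID 352, ASD 205, epilepsy 84,
#' microcephaly 45, macrocephaly 47, hypotonia 71, ataxia 30; explicit
#' known-negative counts for hypotonia (254) and ataxia (285), the remaining
#' patients of those traits being unknown; for the other traits every
#' non-positive patient is negative.
#'
#' @param n_patients Cohort size.
#' @param positive_counts Named integer vector over the traits.
#' @param negative_counts Named integer vector; `NA` entries (the default for
#'   most traits) mean `n_patients - positives`.
#' @param seed Generator seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 415,
                        positive_counts = c(ID = 352, ASD = 205,
                                            Epilepsy = 84, Microcephaly = 45,
                                            Macrocephaly = 47, Hypotonia = 71,
                                            Ataxia = 30),
                        negative_counts = c(Hypotonia = 254, Ataxia = 285),
                        seed = 1) {
  traits <- names(positive_counts)
  neg <- stats::setNames(rep(NA_integer_, length(traits)), traits)
  neg[names(negative_counts)] <- negative_counts
  neg[is.na(neg)] <- n_patients - positive_counts[is.na(neg)]
  if (any(positive_counts + neg > n_patients))
    stopf("positive + negative counts exceed cohort size for trait(s): %s",
          paste(traits[positive_counts + neg > n_patients], collapse = ", "))
  structure(list(n_patients = as.integer(n_patients),
                 positive_counts = positive_counts,
                 negative_counts = neg, seed = seed),
            class = "cohort_spec")
}

#' Generate a phenotype answer key with exact marginals
#'
#' Each trait column independently receives exactly the specified number of
#' positive and negative labels (remainder unknown) by a seeded shuffle —
#' marginal counts are exact on every seed, the joint structure is
#' product-of-marginals.
#'
#' @param spec A [cohort_spec()].
#' @return A `phenotype_answer_key` with patient ids `PT0001`, `PT0002`, ...
#' @export
generate_truth <- function(spec) {
  n <- spec$n_patients
  ids <- sprintf("PT%04d", seq_len(n))
  traits <- names(spec$positive_counts)
  labels <- matrix("unknown", n, length(traits),
                   dimnames = list(ids, traits))
  for (tr in traits) {
    npos <- spec$positive_counts[[tr]]; nneg <- spec$negative_counts[[tr]]
    col <- c(rep("positive", npos), rep("negative", nneg),
             rep("unknown", n - npos - nneg))
    labels[, tr] <- with_seed(derive_seed(spec$seed, "truth", tr),
                              sample(col))
  }
  phenotype_answer_key(labels)
}

#' Specification of a synthetic variant answer key
#'
#' Defaults emulate the challenge key: 217 classified entries — 60 disease
#' causing, 54 likely pathogenic and 103 contributing factor — distributed
#' over 217 diagnosed patients (each gets at least one).
#'
#' @param n_dc,n_lp,n_cf Entries per class.
#' @param n_diagnosed_patients Number of patients carrying at least one
#'   entry.
#' @param gene_regions Panel regions the variants are planted in.
#' @param seed Generator seed.
#' @return Object of class `variant_key_spec`.
#' @export
variant_key_spec <- function(n_dc = 60, n_lp = 54, n_cf = 103,
                             n_diagnosed_patients = 217,
                             gene_regions = default_gene_regions(),
                             seed = 1) {
  total <- n_dc + n_lp + n_cf
  if (total < n_diagnosed_patients)
    stopf("fewer entries (%d) than diagnosed patients (%d)", total,
          n_diagnosed_patients)
  structure(list(n_dc = n_dc, n_lp = n_lp, n_cf = n_cf,
                 n_diagnosed_patients = n_diagnosed_patients,
                 gene_regions = validate_regions(gene_regions), seed = seed),
            class = "variant_key_spec")
}

# Draw n distinct random variants inside the panel regions (SNVs and short
# indels), avoiding identities already in `taken` (a character set of
# chrom:pos:ref:alt tokens).  Batched rejection sampling.
random_panel_variants <- function(n, gene_regions, taken = character(0),
                                  indel_frac = 0.2) {
  if (n == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(len) vapply(len, function(l)
    paste(sample(bases, l, replace = TRUE), collapse = ""), character(1))
  acc <- NULL
  made <- character(0)
  rounds <- 0L
  while (is.null(acc) || nrow(acc) < n) {
    rounds <- rounds + 1L
    if (rounds > 200L)
      stopf("panel regions too small to place %d distinct variants", n)
    m <- 2L * max(n - NROW(acc), 16L)
    r <- sample.int(nrow(gene_regions), m, replace = TRUE)
    # half-open 0-based [start, end) -> 1-based positions start+1 .. end
    width <- gene_regions$end[r] - gene_regions$start[r]
    pos <- gene_regions$start[r] + floor(stats::runif(m) * width) + 1L
    ref <- sample(bases, m, replace = TRUE)
    alt <- character(m)
    is_indel <- stats::runif(m) < indel_frac
    snv <- which(!is_indel)
    alt[snv] <- vapply(ref[snv],
                       function(b) sample(setdiff(bases, b), 1L), character(1))
    if (any(is_indel)) {
      len <- sample.int(3L, m, replace = TRUE)
      del <- is_indel & stats::runif(m) < 0.5
      ins <- is_indel & !del
      alt[del] <- ref[del]
      ref[del] <- paste0(ref[del], rand_seq(len[del]))
      alt[ins] <- paste0(ref[ins], rand_seq(len[ins]))
    }
    cand <- data.frame(chrom = gene_regions$chrom[r], pos = as.integer(pos),
                       ref = ref, alt = alt, stringsAsFactors = FALSE)
    tok <- paste(cand$chrom, cand$pos, cand$ref, cand$alt, sep = ":")
    keep <- !(tok %in% taken) & !(tok %in% made) & !duplicated(tok)
    made <- c(made, tok[keep])
    acc <- rbind(acc, cand[keep, , drop = FALSE])
  }
  acc <- acc[seq_len(n), , drop = FALSE]
  rownames(acc) <- NULL
  acc
}

#' Generate a classified variant answer key
#'
#' Selects the diagnosed patients preferentially among trait-positive ones
#' (sampling weight grows with the number of positive traits), gives each
#' diagnosed patient at least one entry, distributes the remaining entries at
#' random, shuffles class labels over entries, and plants each variant at a
#' random position inside a random panel region (SNV or short indel, unique
#' per cohort).
#'
#' @param spec A [variant_key_spec()].
#' @param truth A `phenotype_answer_key` (supplies the patients and their
#'   trait positivity).
#' @return A `variant_answer_key`.
#' @export
generate_variant_key <- function(spec, truth) {
  ids <- rownames(truth)
  if (spec$n_diagnosed_patients > length(ids))
    stopf("more diagnosed patients requested than cohort size")
  total <- spec$n_dc + spec$n_lp + spec$n_cf
  with_seed(derive_seed(spec$seed, "variant_key"), {
    n_pos_traits <- rowSums(unclass(truth) == "positive")
    diagnosed <- sample(ids, spec$n_diagnosed_patients,
                        prob = 1 + 3 * n_pos_traits)
    carrier <- c(diagnosed,
                 sample(diagnosed, total - length(diagnosed), replace = TRUE))
    classes <- sample(rep(VARIANT_CLASSES, c(spec$n_dc, spec$n_lp, spec$n_cf)))
    vars <- random_panel_variants(total, spec$gene_regions)
    variant_answer_key(carrier, vars, classes)
  })
}

#' Generate one patient's panel VCF records
#'
#' Emits the patient's planted answer-key variants with high quality
#' (QUAL >= 100, DP >= 50, GQ >= 90), `Poisson(background_rate)` benign
#' high-quality background variants, and `Poisson(decoy_rate)` decoy records
#' emulating sequencing errors — each decoy fails at least one of the quality
#' cuts QUAL < 20, DP < 10, GQ < 20 used by [vcf_quality_pass()].
#'
#' @param patient_id Patient identifier.
#' @param key The cohort's `variant_answer_key` (entries of other patients
#'   are ignored).
#' @param gene_regions Panel regions.
#' @param background_rate,decoy_rate Poisson means per patient.
#' @param seed Seed for this patient's records.
#' @return Data frame of VCF records in [read_vcf()] layout, sorted by
#'   chromosome and position, ready for [write_vcf()].
#' @export
generate_patient_vcf <- function(patient_id, key,
                                 gene_regions = default_gene_regions(),
                                 background_rate = 240, decoy_rate = 25,
                                 seed = 1) {
  mine <- as.data.frame(key)[key$patient_id == patient_id,
                             c("chrom", "pos", "ref", "alt"), drop = FALSE]
  with_seed(seed, {
    high <- function(n) data.frame(
      qual = round(stats::runif(n, 100, 900), 1),
      dp = sample(50:250, n, replace = TRUE),
      gq = sample(90:99, n, replace = TRUE),
      gt = sample(c("0/1", "1/1"), n, replace = TRUE, prob = c(0.8, 0.2)))
    taken <- paste(mine$chrom, mine$pos, mine$ref, mine$alt, sep = ":")
    n_bg <- stats::rpois(1, background_rate)
    bg <- random_panel_variants(n_bg, gene_regions, taken = taken)
    taken <- c(taken, paste(bg$chrom, bg$pos, bg$ref, bg$alt, sep = ":"))
    n_decoy <- stats::rpois(1, decoy_rate)
    decoy <- random_panel_variants(n_decoy, gene_regions, taken = taken)
    dq <- high(n_decoy)
    if (n_decoy) {
      # force >= 1 failing quality cut per decoy record
      mode <- sample.int(3L, n_decoy, replace = TRUE)
      dq$qual[mode == 1L] <- round(stats::runif(sum(mode == 1L), 0, 19.9), 1)
      dq$dp[mode == 2L] <- sample(1:9, sum(mode == 2L), replace = TRUE)
      dq$gq[mode == 3L] <- sample(1:19, sum(mode == 3L), replace = TRUE)
    }
    rec <- rbind(cbind(rbind(mine, bg), high(nrow(mine) + n_bg)),
                 cbind(decoy, dq))
    rec <- rec[, c("chrom", "pos", "ref", "alt", "qual", "gt", "dp", "gq")]
    rec[order(rec$chrom, rec$pos), , drop = FALSE]
  })
}

#' Quality filter for VCF records
#'
#' The decoy-exclusion rule: a record passes iff `QUAL >= min_qual`,
#' `DP >= min_dp` and `GQ >= min_gq`.  Applied to generated patient VCFs this
#' removes exactly the decoy records.
#'
#' @param records Data frame in [read_vcf()] layout.
#' @param min_qual,min_dp,min_gq Cut constants (defaults 20, 10, 20).
#' @return Logical vector, one element per record.
#' @export
vcf_quality_pass <- function(records, min_qual = 20, min_dp = 10,
                             min_gq = 20) {
  records$qual >= min_qual & records$dp >= min_dp & records$gq >= min_gq
}

#' Skill profile of a simulated predictor
#'
#' Binormal phenotype model: for a trait with separation `mu`, positive
#' patients draw a latent score from `Normal(mu, 1)` and the rest from
#' `Normal(0, 1)`; the submitted probability is the logistic of the score, so
#' the expected ROC AUC is `pnorm(mu / sqrt(2))`.  `target_auc` is the
#' user-facing dial and is converted to `mu`.
#'
#' @param target_auc Expected ROC AUC per trait (scalar or named vector over
#'   `traits`), in `[0.5, 1)`.
#' @param miss_rate Probability a cell is emitted as missing (`"*"`).
#' @param variant_sensitivity Probability a key variant is predicted.
#' @param variant_fp_per_patient Poisson mean of spurious predicted variants
#'   per patient.
#' @param traits Trait names.
#' @return Object of class `skill_profile` with per-trait `mu`.
#' @export
skill_profile <- function(target_auc = 0.75, miss_rate = 0.02,
                          variant_sensitivity = 0.8,
                          variant_fp_per_patient = 0.3,
                          traits = panel_traits()) {
  if (any(target_auc < 0.5 | target_auc >= 1))
    stopf("target_auc must lie in [0.5, 1)")
  auc <- rep_len(target_auc, length(traits))
  names(auc) <- traits
  structure(list(target_auc = auc,
                 mu = sqrt(2) * stats::qnorm(auc),
                 miss_rate = miss_rate,
                 variant_sensitivity = variant_sensitivity,
                 variant_fp_per_patient = variant_fp_per_patient,
                 traits = traits),
            class = "skill_profile")
}

#' Simulate a phenotype probability submission
#'
#' Draws the binormal latent scores of [skill_profile()], maps them through
#' the logistic, and blanks each cell independently with the profile's miss
#' rate.
#'
#' @param truth A `phenotype_answer_key`.
#' @param profile A `skill_profile`.
#' @param seed Seed.
#' @param submission_id,group_id Identifiers for the result.
#' @return A `phenotype_submission`.
#' @export
simulate_phenotype_submission <- function(truth, profile, seed = 1,
                                          submission_id = "1.1",
                                          group_id = submission_group(submission_id)) {
  lab <- unclass(truth)
  n <- nrow(lab)
  probs <- matrix(NA_real_, n, ncol(lab), dimnames = dimnames(lab))
  with_seed(seed, {
    for (tr in colnames(lab)) {
      mu <- profile$mu[[tr]]
      score <- stats::rnorm(n) + mu * (lab[, tr] == "positive")
      probs[, tr] <- stats::plogis(score)
    }
    if (profile$miss_rate > 0)
      probs[stats::runif(length(probs)) < profile$miss_rate] <- NA_real_
  })
  phenotype_submission(probs, submission_id, group_id)
}

#' Simulate a variant prediction submission
#'
#' Includes each answer-key entry independently with the profile's
#' sensitivity and adds, per patient, `Poisson(variant_fp_per_patient)`
#' spurious predictions at panel positions not present in the key.
#'
#' @param key A `variant_answer_key`.
#' @param profile A `skill_profile`.
#' @param patient_ids Patients that may receive false positives; defaults to
#'   the key's patients (pass the full cohort for cohort-wide noise).
#' @param gene_regions Panel regions for spurious variants.
#' @param seed Seed.
#' @param submission_id,group_id Identifiers for the result.
#' @return A `variant_prediction_set`.
#' @export
simulate_variant_submission <- function(key, profile,
                                        patient_ids = unique(key$patient_id),
                                        gene_regions = default_gene_regions(),
                                        seed = 1, submission_id = "1.1",
                                        group_id = submission_group(submission_id)) {
  with_seed(seed, {
    keep <- stats::runif(nrow(key)) < profile$variant_sensitivity
    hits <- as.data.frame(key)[keep, c("patient_id", "chrom", "pos", "ref",
                                       "alt"), drop = FALSE]
    n_fp <- stats::rpois(length(patient_ids), profile$variant_fp_per_patient)
    taken <- paste(key$chrom, key$pos, key$ref, key$alt, sep = ":")
    fp <- if (sum(n_fp) > 0) {
      v <- random_panel_variants(sum(n_fp), gene_regions, taken = taken)
      cbind(data.frame(patient_id = rep(patient_ids, n_fp),
                       stringsAsFactors = FALSE), v)
    } else NULL
    df <- rbind(hits, fp)
    variant_prediction_set(df$patient_id,
                           df[, c("chrom", "pos", "ref", "alt")],
                           submission_id = submission_id,
                           group_id = group_id)
  })
}
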