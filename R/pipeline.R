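## End-to-end glue: synthesize a challenge, assess both tracks, rank, and
## emit the leaderboard/coverage/consensus TSVs.

#' Default simulated predictor panel
#'
#' Four groups of strictly ordered skill (target ROC AUC 0.55, 0.65, 0.75,
#' 0.85) with variant sensitivities and false-positive rates spanning the
#' regimes observed across real submissions (from low-recall/low-precision to
#' the 0.82-sensitivity / ~0.3 FP-per-patient regime of the strongest
#' predictor).
#'
#' @return Named list of [skill_profile()] objects keyed by submission id.
#' @export
default_profiles <- function() {
  list("1.1" = skill_profile(0.55, miss_rate = 0.05, variant_sensitivity = 0.30,
                             variant_fp_per_patient = 1.5),
       "2.1" = skill_profile(0.65, miss_rate = 0.02, variant_sensitivity = 0.50,
                             variant_fp_per_patient = 0.8),
       "3.1" = skill_profile(0.75, miss_rate = 0.02, variant_sensitivity = 0.70,
                             variant_fp_per_patient = 0.4),
       "4.1" = skill_profile(0.85, miss_rate = 0.01, variant_sensitivity = 0.82,
                             variant_fp_per_patient = 0.3))
}

#' Synthesize a complete challenge data set
#'
#' Generates the phenotype answer key, the classified variant key, one
#' submission pair (phenotype probabilities + variant predictions) per skill
#' profile and, optionally, per-patient panel VCFs; writes everything to
#' `out_dir` in the on-disk dialects of the IO module when a directory is
#' given.
#'
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param cspec A [cohort_spec()].
#' @param vspec A [variant_key_spec()].
#' @param profiles Named list of [skill_profile()]s keyed by submission id.
#' @param seed Master seed (overrides the seeds in `cspec`/`vspec`).
#' @param write_vcfs Write per-patient VCF files (slowest part; off by
#'   default).
#' @param background_rate,decoy_rate Passed to [generate_patient_vcf()].
#' @return List: `cohort`, `truth`, `key`, `phenotype_submissions`,
#'   `variant_submissions`, `paths` (when written).
#' @export
synthesize_challenge <- function(out_dir = NULL,
                                 cspec = cohort_spec(),
                                 vspec = variant_key_spec(),
                                 profiles = default_profiles(),
                                 seed = NULL,
                                 write_vcfs = FALSE,
                                 background_rate = 240, decoy_rate = 25) {
  if (!is.null(seed)) {
    cspec$seed <- derive_seed(seed, "cohort")
    vspec$seed <- derive_seed(seed, "variants")
  }
  truth <- generate_truth(cspec)
  key <- generate_variant_key(vspec, truth)
  cohort <- cohort_definition(rownames(truth), colnames(truth),
                              vspec$gene_regions)
  phen <- list(); varp <- list()
  for (sid in names(profiles)) {
    phen[[sid]] <- simulate_phenotype_submission(
      truth, profiles[[sid]], seed = derive_seed(cspec$seed, "phen", sid),
      submission_id = sid)
    varp[[sid]] <- simulate_variant_submission(
      key, profiles[[sid]], patient_ids = cohort$patient_ids,
      gene_regions = vspec$gene_regions,
      seed = derive_seed(vspec$seed, "varsub", sid), submission_id = sid)
  }
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sub_dir <- file.path(out_dir, "submissions")
    dir.create(sub_dir, showWarnings = FALSE)
    write_phenotype_answer_key(truth, file.path(out_dir, "phenotype_key.tsv"))
    write_variant_answer_key(key, file.path(out_dir, "variant_key.tsv"))
    write_bed(cohort$gene_regions, file.path(out_dir, "panel.bed"))
    writeLines(cohort$patient_ids, file.path(out_dir, "patients.txt"))
    for (sid in names(profiles)) {
      write_phenotype_submission(phen[[sid]],
        file.path(sub_dir, sprintf("phenotypes_%s.tsv", sid)))
      write_variant_predictions(varp[[sid]],
        file.path(sub_dir, sprintf("variants_%s.tsv", sid)))
    }
    if (write_vcfs) {
      vcf_dir <- file.path(out_dir, "vcf")
      dir.create(vcf_dir, showWarnings = FALSE)
      for (p in cohort$patient_ids) {
        rec <- generate_patient_vcf(p, key, cohort$gene_regions,
                                    background_rate, decoy_rate,
                                    seed = derive_seed(cspec$seed, "vcf", p))
        write_vcf(rec, file.path(vcf_dir, paste0(p, ".vcf")), sample_id = p)
      }
    }
    paths <- list(dir = out_dir, submissions = sub_dir)
  }
  list(cohort = cohort, truth = truth, key = key,
       phenotype_submissions = phen, variant_submissions = varp,
       paths = paths)
}

#' Assess every variant submission of a challenge
#'
#' @param variant_submissions Named list of `variant_prediction_set`s.
#' @param key The `variant_answer_key`.
#' @param reference Optional reference sequences for left alignment.
#' @return List: `matches` (per submission), `scores` (leaderboard data frame
#'   with `n_correct`, `n_predicted`, `n_key`, `recall`, `accuracy` rounded
#'   to 3 decimals), `coverage` (long data frame of per-class coverage), and
#'   `consensus` (a `consensus_histogram` over group unions).
#' @export
assess_variants <- function(variant_submissions, key, reference = NULL) {
  matches <- lapply(variant_submissions, match_patient_variants, key = key,
                    reference = reference)
  scores <- do.call(rbind, lapply(names(matches), function(sid) {
    s <- cohort_score(matches[[sid]])
    data.frame(submission_id = sid,
               n_correct = s$n_correct, n_predicted = s$n_predicted,
               n_key = s$n_key,
               recall = round(s$recall, 3), accuracy = round(s$accuracy, 3),
               stringsAsFactors = FALSE)
  }))
  coverage <- do.call(rbind, lapply(names(matches), function(sid) {
    cbind(submission_id = sid,
          as.data.frame(class_coverage(matches[[sid]], key)))
  }))
  groups <- split(names(variant_submissions),
                  submission_group(names(variant_submissions)))
  group_matches <- lapply(names(groups), function(g) {
    u <- suppressMessages(
      group_prediction_union(variant_submissions[groups[[g]]], group_id = g))
    match_patient_variants(u, key, reference = reference)
  })
  names(group_matches) <- names(groups)
  list(matches = matches, scores = scores, coverage = coverage,
       consensus = consensus_histogram(group_matches, key))
}

#' Run the full assessment on a synthetic challenge
#'
#' The complete loop the package exists for, on generated data: synthesize a
#' cohort and submissions, assess the phenotype track (MCC thresholds,
#' metrics, bootstrap AUC), assess the variant track (matching, recall /
#' accuracy, class coverage, consensus), rank submissions by mean per-trait
#' z-score, and re-run the phenotype assessment on the diagnosed subset.
#' With `out_dir` set, leaderboard- and figure-shaped TSVs are written.
#'
#' @inheritParams synthesize_challenge
#' @param n_boot Bootstrap iterations per (submission, trait).
#' @param subset_rerun Also re-assess on the diagnosed subset.
#' @return List: `data` (the synthesized challenge), `phenotype`
#'   (`phenotype_assessment`), `zscores`, `variant` (see
#'   [assess_variants()]), `phenotype_consensus`, and `subset` (diagnosed
#'   subset rerun, when requested).
#' @export
run_id_challenge <- function(out_dir = NULL, seed = 1,
                             cspec = cohort_spec(),
                             vspec = variant_key_spec(),
                             profiles = default_profiles(),
                             n_boot = 1000, subset_rerun = TRUE,
                             write_vcfs = FALSE) {
  data <- synthesize_challenge(out_dir = out_dir, cspec = cspec,
                               vspec = vspec, profiles = profiles,
                               seed = seed, write_vcfs = write_vcfs)
  phen <- assess_phenotypes(data$phenotype_submissions, data$truth,
                            n_boot = n_boot,
                            seed = derive_seed(seed, "assess"))
  zs <- zscore_by_trait(auc_matrix(phen))
  varres <- assess_variants(data$variant_submissions, data$key)
  cons <- group_consensus(group_binarized(phen), data$truth)
  subset_res <- NULL
  if (subset_rerun) {
    ids <- diagnosed_subset(data$key, data$cohort)
    subset_res <- rerun_on_subset(data$phenotype_submissions, data$truth,
                                  ids, n_boot = n_boot,
                                  seed = derive_seed(seed, "subset"))
  }
  if (!is.null(out_dir)) {
    wt <- function(df, name) utils::write.table(
      df, file.path(out_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(phen$metrics, "phenotype_metrics.tsv")
    wt(zscore_leaderboard(zs), "phenotype_ranking.tsv")
    wt(varres$scores, "variant_scores.tsv")
    wt(varres$coverage, "variant_class_coverage.tsv")
    wt(varres$consensus$histogram, "variant_consensus.tsv")
    wt(cons$histogram, "phenotype_consensus.tsv")
    if (!is.null(subset_res))
      wt(zscore_leaderboard(subset_res$zscores), "phenotype_ranking_subset.tsv")
  }
  list(data = data, phenotype = phen, zscores = zs, variant = varres,
       phenotype_consensus = cons, subset = subset_res)
}
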