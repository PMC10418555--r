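# panelbench

Assessment pipeline for blind prediction challenges on targeted gene-panel
cohorts of children with neurodevelopmental disorders (NDDs). In such a
challenge, a clinical laboratory sequences a cohort with a gene panel (here:
415 patients, 74 genes) and withholds its answer key — seven tri-state
phenotype labels per patient (intellectual disability, autism spectrum
disorder, epilepsy, microcephaly, macrocephaly, hypotonia, ataxia) and the
classified causal variants (disease causing DC, likely pathogenic LP,
contributing factor CF). Participating teams submit, per patient, a
probability for each trait and a list of candidate causal variants.
`panelbench` is the assessor's side: it scores those submissions and ranks
the predictors. Because the patient data cannot be released, the package also
ships a synthetic cohort generator with the same marginal structure, so the
entire assessment is reproducible end to end.

## What it computes

**Phenotype track.** Missing cells (`"*"`) are scored as probability 0. Each
trait column is binarized at the threshold t maximizing the Matthews
correlation coefficient of the rule p ≥ t,

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

with accuracy, F1, sensitivity and specificity reported at that operating
point (patients whose truth label is unknown are excluded from the counts).
ROC and precision–recall curves are computed per trait, with AUC estimated
over 1000 bootstrap resamples of the patients. Submissions are ranked by the
mean over traits of the per-trait z-score of AUC,
z = (AUC − mean)/sd across submissions.

**Variant track.** A predicted (patient, variant) pair is a true positive
iff it matches an answer-key entry after representation normalization
(allele trimming, optional reference left-alignment). Per submission:

    recall   = correctly predicted variants / answer-key variants
    accuracy = correctly predicted variants / predicted variants

("accuracy" is the challenge's term; it is precision under standard naming).
Per-class coverage (DC/LP/CF) and cross-group consensus histograms — how many
groups recovered each key variant — complete the report.

**Synthetic cohort.** `generate_truth()` reproduces the cohort's per-trait
positive/negative counts exactly; `generate_variant_key()` plants 217
classified variants (60 DC, 54 LP, 103 CF) over 217 diagnosed patients;
`generate_patient_vcf()` emits panel VCFs with high-quality planted and
background variants plus low-quality decoy records that the documented
QUAL/DP/GQ cuts remove exactly; `simulate_phenotype_submission()` and
`simulate_variant_submission()` create submissions of tunable skill (binormal
score model with expected AUC Φ(μ/√2)).

## Worked example

Scoring the published count triple of the strongest variant predictor
(178 correct of 303 predicted, against a 217-variant key):

```r
library(panelbench)
cohort_score(list(n_correct = 178, n_predicted = 303, n_key = 217))
#> <cohort_variant_score> 178/217 key (recall 0.820), 303 predicted (accuracy 0.587)
```

A full synthetic challenge — four simulated predictors of increasing skill
(target AUC 0.55/0.65/0.75/0.85, variant sensitivity 0.30–0.82) — assessed
end to end:

```r
res <- run_id_challenge(seed = 7, n_boot = 200)
zscore_leaderboard(res$zscores)
#>   submission_id      ID     ASD Epilepsy Microcephaly Macrocephaly Hypotonia  Ataxia  mean_z rank
#> 1           4.1  1.1624  1.0863   0.8645       1.0661       1.0826    1.1776  0.9315  1.0530    1
#> 2           3.1  0.2533  0.4717   0.7912       0.5811       0.4479    0.4015  0.7966  0.5347    2
#> 3           2.1 -0.1681 -0.3409  -0.4701      -0.5327      -0.2876   -0.4693 -0.8155 -0.4406    3
#> 4           1.1 -1.2476 -1.2171  -1.1856      -1.1144      -1.2428   -1.1098 -0.9125 -1.1471    4

res$variant$scores
#>   submission_id n_correct n_predicted n_key recall accuracy
#> 1           1.1        59         674   217  0.272    0.088
#> 2           2.1       109         425   217  0.502    0.256
#> 3           3.1       152         323   217  0.700    0.471
#> 4           4.1       183         315   217  0.843    0.581
```

The ranking recovers the planted skill order exactly, and each simulated
predictor's recall tracks its sensitivity dial. Passing an `out_dir` writes
the leaderboard-, coverage- and consensus-shaped TSVs. The same pipeline is
available from the shell via the installed `exec/panelbench` script
(`synth`, `assess-phenotypes`, `assess-variants`, `rank` subcommands).

## Package layout

- `R/io_formats.R` — submission/answer-key TSV dialects, minimal
  single-sample VCF 4.2 (via vcfR) and BED4 readers/writers, validation.
- `R/phenotype_assessment.R` — imputation, MCC-optimal thresholds, confusion
  metrics, ROC/PR AUC, bootstrap.
- `R/variant_assessment.R` — variant normalization, matching, recall and
  accuracy, class coverage, consensus.
- `R/ranking_report.R` — z-score leaderboards, diagnosed-subset re-analysis,
  phenotype group consensus.
- `R/synthetic_cohort.R` — cohort/key/VCF/submission generators.
- `vignettes/assessment-methods.Rmd` — the model, its conventions and the
  design decisions in detail.
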