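---
title: "Assessment methods for gene-panel prediction challenges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessment methods for gene-panel prediction challenges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelbench)
```

# The assessment problem

A clinical laboratory sequences a cohort of pediatric patients with
neurodevelopmental disorders on a targeted gene panel and keeps two ground
truths: per-patient tri-state labels (positive / negative / unknown) for
seven clinical traits, and a per-patient list of classified variants —
disease causing (DC), likely pathogenic or "putative" (LP), and contributing
factor (CF, variants in autism-susceptibility genes that are insufficient
alone to cause disease). Blinded teams submit (a) a probability per patient
and trait and (b) zero or more candidate causal variants per patient.
`panelbench` scores both tracks and ranks the submissions.

Two structural facts drive most design choices. First, the truth is
genuinely tri-state: for some traits the laboratory's positive and negative
counts do not cover the cohort (e.g. hypotonia: 71 positive and 254 negative
of 415), so an "unknown" label must be representable and must not be
silently counted as negative. Second, the trait prevalences are wildly
imbalanced (intellectual disability in 352/415 patients, ataxia in 30/415),
which is why the binarization criterion is the Matthews correlation
coefficient rather than accuracy, and why AUCs are complemented with
per-trait standardization before ranking.

# Phenotype track

## Missing cells

Predictors may leave a cell blank (`"*"` on the template). The scoring rule
is that a blank counts as probability zero. The IO layer deliberately
preserves blanks as `NA` so the file remains auditable; `impute_missing()`
applies the zero rule as the first step of `assess_phenotypes()`.

## MCC-optimal binarization

For each trait, `optimal_mcc_threshold()` converts probabilities to 0/1 at
the threshold maximizing the MCC. Conventions, chosen for exhaustive
checkability:

* prediction rule is `p >= t` (positive at the threshold);
* candidate thresholds are the midpoints between consecutive distinct
  probability values, plus one sentinel below the minimum (predict all
  positive) and one above the maximum (predict all negative) — no other
  threshold produces a distinct binarization;
* ties in MCC are broken toward the *smallest* threshold, i.e. the more
  sensitive operating point;
* MCC with a zero factor in its denominator is defined as 0 (the standard
  convention; it keeps the range [-1, 1] and makes the all-positive and
  all-negative sentinels score 0 rather than be undefined);
* patients with unknown truth get a binarized prediction (they are needed
  downstream for consensus counts) but are excluded from the optimization
  and from all confusion counts. The switch `unknown_as_negative = TRUE`
  reproduces the stricter reading in which unlabeled patients count as
  negatives.

Sensitivity, specificity, accuracy and F1 are reported at the MCC-optimal
threshold and labeled as such; whether a different operating point should be
used for them is genuinely open, and computing everything at one documented
point makes the numbers mutually consistent.

## ROC, PR and the bootstrap

`roc_auc()` computes the threshold-sweep ROC with tied scores collapsed into
single curve points and trapezoidal area; this is numerically identical to
the Mann–Whitney U statistic with ties counted one half, and the test suite
enforces that identity against an independent pair-counting oracle.
`pr_auc()` uses the average-precision summation (rectangles, no
interpolation of precision), under which a constant predictor scores the
prevalence — the honest baseline for imbalanced traits.

`bootstrap_auc()` resamples the known-label patients with replacement to the
same size, 1000 iterations by default, and records both AUCs per iteration.
The bootstrap is unstratified by default: a resample that collapses to a
single class is discarded and redrawn (cap: 100 consecutive redraws, then an
error advising `stratified = TRUE`, which resamples within classes). For the
cohort sizes at hand the redraw is a rare event; the cap only triggers for
pathologically small classes, where the stratified mode is the right tool
anyway.

Seeding: each (submission, trait) bootstrap runs on its own seed derived
from the master seed by stable string hashing (`derive_seed()`). Adding or
removing a submission therefore never changes any other submission's
bootstrap draw — a property the tests assert explicitly.

## Ranking

`zscore_by_trait()` standardizes each trait column of the submissions x
traits AUC matrix with the sample (n−1) standard deviation, and ranks by the
unweighted mean z over traits; ties break by submission id. A constant
column maps to all-zero z rather than dividing by zero. The ranking input is
the mean bootstrap ROC AUC (`auc_matrix(assessment, "boot_mean")`), which is
the quantity the leaderboard standardizes; `auc_matrix(assessment, "point")`
provides the single-pass alternative. The package's skill-recovery check
(four simulated predictors with target AUC 0.55/0.65/0.75/0.85 on the
default 415-patient cohort, 100 generator seeds) uses the point-AUC input:
for a rank-recovery property the bootstrap average adds Monte-Carlo cost but
no discriminative information, since its expectation is monotone in the same
underlying AUC.

`rerun_on_subset()` repeats the identical pipeline on a patient subset —
typically `diagnosed_subset()`, the patients carrying at least one key
variant — re-optimizing thresholds on the subset. Traits left single-class
by the restriction are dropped from the subset ranking with a warning.

`group_consensus()` aggregates binarized predictions to groups (a research
group may file several model submissions): a group is correct for a
truth-positive patient if at least one of its submissions predicts positive
(`mode = "all"` gives the strict variant), and the per-trait histogram over
the number of correct groups sums to the trait's positive count.

# Variant track

## Matching

Identity is (patient, chromosome, position, ref, alt) after normalization;
predicted class labels are ignored for matching, since the truth of "this
variant explains this patient" does not depend on the submitted class.
`normalize_variant()` trims the shared allele suffix, then the shared prefix
(keeping at least one base each side, adjusting position), and — when a
reference sequence is supplied — left-aligns indels before prefix trimming.
Both the trim-only and the reference mode are exposed because whether the
original assessment normalized representations is unknowable from the
outside; trim-only is the default as it requires no reference and already
unifies the common padded spellings. The operation is idempotent, which the
suite property-tests on random alleles.

Duplicate predicted (patient, variant) entries are removed at construction
with a message: repeated listing must not inflate `n_predicted` (it would
otherwise *deflate* accuracy, but also allow recall gaming in the other
direction if duplicates were counted as multiple hits).

## Scores

`cohort_score()` reports recall = n_correct / n_key and accuracy =
n_correct / n_predicted, keeping the challenge's use of "accuracy" for what
is precision in standard nomenclature (the glossary-level renaming is noted
wherever the value is documented). Zero denominators yield `NA`, not 0 — an
empty prediction set has undefined precision, not perfect or zero precision.
Reported tables round to 3 decimals, which is exactly invertible back to
integer counts at these cohort sizes (a property the suite checks).
`class_coverage()` is the same numerator restricted per class, as a
percentage of the class's key entries. `consensus_histogram()` counts, per
key entry, the number of groups whose union-of-submissions predictions
recovered it; group unions (not individual submissions) are the granularity
used, because the per-submission leaderboard and the per-group consensus
answer different questions.

# The synthetic cohort

The generator exists so the full pipeline can run, and be tested, with no
access to the real patient data. What it reproduces and what it does not:

* **Phenotype marginals, exactly.** `generate_truth()` assigns per trait
  exactly the configured positive and negative counts (defaults: positives
  352/205/84/45/47/71/30 for the seven traits; explicit negatives 254 for
  hypotonia and 285 for ataxia, the rest unknown; all other traits fully
  labeled). Columns are shuffled independently, so the joint structure is
  product-of-marginals — real comorbidity correlations (ID co-occurring with
  ASD, say) are *not* emulated. Passing tests therefore validate the
  scoring machinery, not any claim about the joint phenotype distribution.
* **Answer-key structure.** Defaults: 217 entries — 60 DC, 54 LP, 103 CF —
  over 217 diagnosed patients, each carrying at least one. The DC total is
  the published count; the overall 217 is the key size consistently implied
  by every leaderboard recall/count pair; the CF total follows from the
  published fraction of sparsely predicted CF variants (37 of them being
  36%), and LP is the remainder. All three are overridable generator
  defaults documented as derived. Diagnosed patients are sampled with
  weight increasing in their number of positive traits, reflecting that
  diagnostic yield concentrates in more heavily affected patients.
* **Panel VCFs.** A toy 74-region panel (one 2 kb region per synthetic gene
  symbol, chromosomes 1–22 and X, no real coordinates) hosts planted key
  variants (QUAL ≥ 100, DP ≥ 50, GQ ≥ 90), Poisson background variants of
  the same quality (default mean 240 per patient, matching the order of
  magnitude of raw panel calls), and Poisson decoy records (default mean 25)
  that each fail at least one of the quality cuts QUAL < 20, DP < 10,
  GQ < 20. The cut constants are package choices — the challenge names the
  fields, not thresholds — and `vcf_quality_pass()` removes exactly the
  decoys by construction, a property the suite asserts. No allele
  frequencies, inheritance, trio structure or sequence context are
  simulated.
* **Submissions.** The binormal model: positives draw a latent score from
  N(μ, 1), everyone else from N(0, 1), submitted probability is the
  logistic of the score, so the expected ROC AUC is Φ(μ/√2) and
  `skill_profile(target_auc = …)` inverts that closed form. Cells go
  missing independently at `miss_rate`. Variant submissions keep each key
  entry with `variant_sensitivity` and add Poisson false positives per
  patient at non-key panel positions. The default four-predictor panel
  spans target AUC 0.55–0.85 and sensitivity 0.30–0.82, bracketing the
  skill range observed across real submissions.

# Numerical conventions and degenerate inputs

* Threshold and AUC computations are exact rational arithmetic in doubles;
  oracle comparisons in the tests use tolerance 1e−12.
* Single-class truth: `optimal_mcc_threshold()` and `roc_auc()` refuse
  (there is no defined threshold or curve); `pr_auc()` requires at least
  one positive; `rerun_on_subset()` drops such traits with a warning
  instead, because a subset rerun should not fail wholesale on one
  degenerate trait.
* `zscore_by_trait()` with one submission warns and returns all-zero z,
  rank 1.
* All seeds are integers below 2^31; `derive_seed()` reduces modulo the
  Mersenne prime 2^31 − 1. Seeded sections save and restore the caller's
  RNG state.

# Problem sizes used by the test suite

The suite checks oracle agreement on 1000 random small instances (n ≤ 12)
per primitive, bootstrap behavior at the full 415-patient scale with 1000
iterations for one trait and 200–300 iterations elsewhere, and the
skill-ranking recovery over 100 generator seeds with point AUCs. These sizes
make the whole suite run in well under a minute while keeping every check at
the cohort scale where it is informative.

# Known limitations

* Joint phenotype structure is independent across traits; correlated-trait
  generation (e.g. a shared latent comorbidity factor) is not implemented.
* The synthetic panel uses arbitrary coordinates and synthetic gene symbols;
  reference-based left-alignment is only exercised with small in-test
  sequences.
* No calibration assessment, no analytic AUC confidence intervals (DeLong),
  and no significance testing of rank differences: the bootstrap SD and the
  z-table are the only dispersion summaries.
* The VCF layer targets the single-sample, unphased files of a panel
  workflow; multi-sample, phased or symbolic-allele records are out of
  scope.
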