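---
title: "Methods: gene-set enrichment guided polygenic risk scores for chronic post-surgical pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-set enrichment guided polygenic risk scores for chronic post-surgical pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chronic post-surgical pain (CPSP) — pain persisting months after surgery,
here dichotomized as a numerical rating scale (NRS) score above 3 at 6–12
months — affects a large fraction of adolescents after spine fusion, yet
cohorts with well-characterized CPSP phenotypes are far too small for
genome-wide association (GWAS). `enrichprs` implements the alternative
analysis route such cohorts support: restrict attention to a biologically
prioritized gene universe, demonstrate that its variants carry an excess of
nominal associations relative to frequency-matched random variants, and build
a weighted polygenic risk score (PRS) from a sparsified subset of the
enriched variants.

The pipeline has seven stages, each exposed as ordinary R functions and
orchestrated by `run_pipeline()`:

1. **Data** — a cohort (VCF genotypes, variant→gene annotation, a ranked gene
   table, phenotypes) is loaded from disk or simulated by `simulate_cohort()`.
2. **QC** (`filter_variants()`, `ld_prune()`) — autosomal, gene-annotated
   variants with call rate ≥ 95%, Hardy–Weinberg goodness-of-fit p ≥ 1e-4 and
   minor allele frequency (MAF) ≥ 10%, LD-pruned in sliding windows of 50
   variants advanced by 5 at an r² ceiling of 0.8.
3. **Association** (`screen_covariates()`, `snp_association()`) — ordinary
   least squares of the *continuous* pain score on the additive-coded
   genotype (0/1/2 minor alleles) plus covariates passing a univariate
   p < 0.1 screen; self-reported race is always carried as a covariate.
4. **Enrichment** (`run_enrichment()`) — the package's core statistic,
   described below.
5. **PRS** (`impute_missing_mode()`, `lasso_select()`, `build_prs_model()`,
   `compute_prs()`) — variants of the minimal enriched set are completed by
   modal imputation, sparsified by dual LASSO, and combined into
   \(PRS_n = \sum_{i=1}^{m} |b_i| \, R_{i,n}\), where \(R_{i,n}\in\{0,1,2\}\)
   counts risk alleles and \(|b_i|\) is the absolute single-variant
   linear-model coefficient.
6. **Models** (`fit_stepwise_logistic()`, `compare_auc()`) — a clinical-only
   and a PRS-augmented logistic model for the dichotomous outcome, compared
   by DeLong's test for correlated AUCs.
7. **Bootstrap** (`bootstrap_validate()`) — 1,000 resamples refitting the
   final model; per-term bias (bootstrap mean − original) and bias-corrected
   coefficients (original − bias) with percentile 95% intervals.

## The enrichment statistic

Candidate genes carry a total order (rank 1 = most functionally similar to a
curated training set of genes with prior CPSP evidence). `cumulative_sets()`
forms eleven nested case variant sets: set 0 is the training-gene variants;
set *k* adds the variants of the top *k*·10% of ranked candidate genes
(ceiling on fractional counts, so the 100% set contains every candidate
gene). For each set, the observed count of variants with association p < 0.05
is compared against the same count in 10,000 random draws from the
control-gene variant pool. Each draw matches the case set's MAF composition
exactly over four bands — [0.10, 0.15), [0.15, 0.20), [0.20, 0.30),
[0.30, 0.50] — and samples without replacement within a draw. The empirical
p-value is the fraction of draws whose significant count equals or exceeds
the observed count (raw count divided by the number of runs; an add-one
Davison–Hinkley corrected version is reported alongside). A set is flagged
*enriched* when its observed count strictly exceeds the 95th percentile
(`stats::quantile`, type 7) of the null counts, and the earliest enriched set
is the *minimal enriched set* that feeds the PRS.

Two properties motivate this construction. First, no per-variant
multiple-testing correction is applied: the resampling null controls the
error of the *set-level* decision by construction, which is the only decision
the pipeline acts on. Second, MAF-band matching removes the main systematic
difference between candidate and random variants that affects nominal
significance rates (power rises with MAF), so the null is competitive rather
than generic.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `alpha` | 0.05 | per-variant nominal significance threshold |
| `n_runs` | 10,000 | matched control draws per set |
| `maf_breaks` | 0.10/0.15/0.20/0.30/0.50 | band edges for matching |
| `increment` | 10% | candidate-gene fraction per cumulative step |
| `call_rate_min`, `hwe_p_min`, `maf_min` | 0.95, 1e-4, 0.10 | QC gates |
| `ld_window`, `ld_step`, `ld_r2_max` | 50, 5, 0.8 | pruning dialect |
| `cv_folds` | 10 | LASSO cross-validation folds (`lambda.min` rule) |
| `entry_p` | 0.05 | stepwise Wald entry/retention threshold |
| `n_boot` | 1,000 | bootstrap resamples |
| `dichotomize_threshold` | 3 | NRS above this = CPSP |

## Design choices in open territory

- **LD-prune removal rule.** PLINK's `indep-pairwise` does not pin which
  member of an offending pair is dropped. Here the pair with the largest r²
  is resolved first (ties by variant order), dropping the lower-MAF member
  and, on a MAF tie, the later genomic position. The rule is frozen so
  pruning is reproducible and testable against a brute-force oracle.
- **HWE test.** The chi-square goodness-of-fit approximation (1 df) is used,
  not the exact test. Against an exact multinomial enumeration oracle the
  approximation agrees to roughly 15% relative error at counts around 30;
  at QC scale (hundreds of samples, threshold 1e-4) the distinction is
  immaterial and the chi-square form is the conventional QC choice.
- **PRS weights.** Weights are the absolute coefficients from the
  single-variant covariate-adjusted linear models, *not* the penalized LASSO
  coefficients: the LASSO is used only for support selection (variants with
  non-zero coefficients in both the linear and the logistic penalized fits),
  keeping the weights interpretable in NRS units per allele.
- **Genotype columns unstandardized in the LASSO** (additive-count scale); a
  `standardize` flag restores glmnet's default behavior.
- **Covariates are excluded from the penalized models**; the selection
  operates on genotypes alone.
- **Empirical p without add-one correction** as the primary report (raw
  count / runs), with the corrected variant alongside; the `enriched` flag
  uses the percentile rule, which is the one-sided equivalent up to ties.
- **Band edges** are left-closed, right-open, with the top band closed, so
  the four bands partition [0.10, 0.50] without gaps.
- **Bootstrap resamples with a single outcome class are redrawn** (not
  skipped), keeping the number of resamples fixed; redraws are counted and a
  warning is raised if they exceed 10%.
- **Stepwise logistic selection** enters the candidate with the smallest
  Wald p-value while below 0.05 and removes entered terms whose p rises to
  or above 0.05. Perfect separation — including the silent variant where the
  deviance collapses to zero without a glm warning — raises an error rather
  than returning an untrustworthy fit.
- **Degenerate inputs.** Monomorphic variants are untestable (beta 0, p 1)
  and are barred from the PRS; zero-variance pairs have undefined r²,
  treated as 0 with a warning; all-missing variants are QC errors.

## The synthetic cohort generator

`simulate_cohort()` generates the full input bundle with a single master
seed fanned out to named substreams (genes, effects, genotypes, phenotypes,
missingness), so each stage's randomness is independently reproducible.
Genotypes are drawn in Hardy–Weinberg proportions at per-variant MAFs
uniform on [0.10, 0.50], with optional within-gene LD from a Gaussian AR(1)
copula (`ld_rho`, default 0.3 — a free testing parameter, not an estimate of
any real cohort). The continuous outcome is

NRS = intercept + Σ β·(minor-allele count) + 0.15·CASI + N(0, 2²),

clamped to the 0–10 scale, with the intercept tuned by quantile matching so
the dichotomized prevalence hits its 40% target; CASI (an anxiety-sensitivity
score) is truncated normal with mean 28.6 and SD 5.5, and the remaining
clinical covariates (age, weight, surgical duration, levels fused, anesthetic
doses, acute-pain summaries) are drawn at realistic adolescent-spine-fusion
scales but carry no planted effect. Defaults emulate the motivating cohort:
131 individuals, a 31-gene training set, 1,305 ranked candidates, a large
control pool, and 30 planted training-gene variants at 0.8 NRS per risk
allele. Missing calls are masked completely at random (1%).

What the generator deliberately does *not* emulate: population structure and
admixture (race is a label with no genetic correlate), reference-panel
haplotype structure (so imputation accuracy claims do not transfer),
genotyping-array artifacts, and informative missingness. Passing tests on
synthetic cohorts therefore validate the statistical machinery — calibration
of the resampling null, selection and weighting arithmetic, model comparison
— not robustness to those real-data complications.

### A note on the NRS floor

Clamping the outcome at 0 is a real feature of pain scores (a large fraction
of the cohort reports no pain) and has a measurable statistical consequence,
demonstrated directly in the test suite: the estimated per-allele effect of
a planted variant on the clamped score is systematically smaller than on the
unclamped score, because variation below the floor is invisible. Planted
signals are therefore harder to detect than a pre-clamp power calculation
suggests, and detection at the original cohort size (n = 131) is not
guaranteed. The validation suites that assert near-certain recovery of the
planted training-gene signal use n = 300 cohorts, where the suite verifies
recovery across all replicates.

## Problem sizes used by the test and acceptance suites

Simulations are scaled so the whole suite runs on a single CPU in minutes,
shrinking the gene universe but never the planted effect sizes, noise,
prevalence target or thresholds:

- desk-scale gene universe: 31 training / 100 candidate / 600 control genes,
  10 variants per gene (~7,300 variants);
- enrichment null calibration: 400 replicate global-null cohorts of 200 case
  and 2,000 pool variants, 1,000 matched draws each;
- minimal-set recovery and end-to-end model comparison: 100 and 50 seeds at
  n = 300;
- Monte-Carlo power checks: 2,000–5,000 replicates;
- bootstrap: 1,000 resamples in the acceptance identity check, 100–300 in
  unit tests.

## Known limitations

- The enrichment draws are variant-level; gene-level (competitive,
  GSEA-style) alternatives are out of scope.
- Modal imputation is a stand-in suitable for the low missingness this
  design produces after QC; it is not reference-panel imputation.
- In-sample AUCs of models whose PRS was selected and weighted on the same
  individuals are optimistic; the bootstrap quantifies coefficient bias but
  external validation is the only honest test of transportability.
- The power helpers use normal approximations (no continuity correction),
  matching conventional design calculations; exact small-sample power will
  differ slightly.
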