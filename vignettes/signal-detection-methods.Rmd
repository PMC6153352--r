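---
title: "Propensity-score signal detection for spontaneous reports: models and design"
author: "pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity-score signal detection for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A spontaneous-reporting pharmacovigilance database is a collection of
individual case reports, each listing the drugs a patient was taking and the
adverse events (AEs) observed.  Signal detection asks, for every
(drug, AE) pair, whether the pair is reported together more than the rest of
the database would lead one to expect — a hypothesis generator for expert
review, not a causal verdict.  The classical screens are *disproportionality
methods*: univariate contrasts of observed versus expected co-report counts.
They are fast, and their test-based decisions plug directly into
false-discovery-rate (FDR) machinery, but they see one drug at a time and so
inherit two well-known biases: *masking* (a heavily reported drug deflates
the expected counts of others) and *co-prescription confounding* (a drug
flagged only because it rides along on reports of a genuinely harmful
companion).

`pvsignal` implements three families of detectors on the individual-report
representation — outcome `Y_j` (AE present), covariates `X_1..X_I` (drug
present):

1. **Univariate reference** (`univariateDetector`): per drug, the logistic
   fit `logit P(Y=1) = b0 + b X_i`, equivalent to a reporting-odds-ratio
   analysis; one-sided Wald p-values, Benjamini–Hochberg (BH) adjustment,
   signals at FDR 5%.
2. **Penalized multiple regression** (`bicLassoDetector`,
   `cislDetector`): the joint model
   `logit P(Y=1) = b0 + sum_i b_i X_i`, fitted under an L1 penalty
   `lambda * sum_i |b_i|`.  Two penalty-selection strategies replace cross
   validation (which optimizes prediction, not support recovery):
   *BIC-lasso* refits every distinct active set along the path without
   penalty and keeps the set minimizing `BIC = -2 ln L + k ln N`, declaring
   as signals all drugs with positive refit coefficients; *CISL* (the
   class-imbalance subsampling lasso) draws `B` outcome-upweighted
   subsamples, fits a path on each, and computes for drug `i` and subsample
   `b` the statistic `pi_hat = (1/E) * #{model sizes eta <= E at which
   beta_i > 0}`, with `E` the largest active-set size seen anywhere;
   a drug is selected when a low quantile (5% or 10%) of its `pi_hat`
   distribution is positive.
3. **Propensity-score (PS) strategies** (`psDetector`): for each drug,
   estimate the probability of exposure given the *other* drugs on the
   report, then test the (drug, AE) association either by *adjustment*
   (`logit P(Y=1) = b0 + b X_i + c e_i`, with the estimated PS `e_i` on the
   probability scale), or by weighted univariate regression under *IPTW*
   (`w = X/e + (1-X)/(1-e)`) or *matching weights*
   (`w = min(e, 1-e) * [X/e + (1-X)/(1-e)]`), which are bounded in [0, 1]
   and target the estimand of one-to-one PS matching without discarding
   reports.  Decisions again go through one-sided p-values, BH, and the
   FDR threshold, which is the practical appeal of the PS route: it keeps
   multiple-testing error control while still accounting for co-reported
   drugs.

The PS itself is estimated in high dimension by one of four methods
(`psBic`, `psCisl`, `psHdps`, `psGtb`): BIC-lasso selection of exposure
predictors; CISL selection with the sign constraint relaxed to "nonzero"
(a PS model wants any predictor of exposure, protective or not); an
hdPS-style confounder ranking; or gradient tree boosting on all co-reported
drugs (learning rate 0.1, other hyperparameters at the library defaults).
The first three feed an unpenalized logistic refit whose fitted
probabilities are the scores.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| eligibility thresholds | `> 3` co-reports, `> 10` total reports | drugs below these margins give numerically fragile per-drug fits; bounds are strict inequalities |
| FDR level | 0.05 | conventional screening level for test-based detectors |
| penalty grid | 50 log-spaced values from `lambda_max` down to `0.01 lambda_max` | `lambda_max` (computed from the data) is the smallest penalty with an empty model, so the grid spans the whole path and makes the CISL normalizer `E` well defined |
| CISL subsamples `B` | 100 | enough resolution for 5%/10% quantiles of `pi_hat` |
| CISL subsample size / case share | `N/2`, expected case fraction 0.25 | with-replacement, outcome-upweighted draws give rare outcomes a workable representation in every subsample |
| hdPS covariates | top 20 by ranking score | standard hdPS practice of keeping a fixed number of top-ranked confounder candidates |
| GTB rounds | 100, learning rate 0.1 | shrinkage small enough to need many rounds; rounds capped for determinism and runtime |
| PS clamp | `[1e-6, 1 - 1e-6]` | protects IPTW from infinite weights when a score saturates |

## Numerical choices

* **Quantile convention.** The CISL selection quantile is the lower
  (type-1) empirical quantile: with `B` subsamples, a drug is selected at
  level `q` exactly when fewer than `ceiling(q * B)` of its `pi_hat` values
  are zero.  Lower `q` is therefore the stricter rule, and
  `selected(0.05)` is always contained in `selected(0.10)` — consistent
  with the 10% variant generating more signals than the 5% one.
* **Path indexing.** When several penalties on one path share an active-set
  size, the most regularised fit of that size is counted once in the CISL
  statistic; sizes that never occur contribute nothing.
* **BIC scan.** Refitting every distinct active set is the dominant cost of
  PS estimation over hundreds of drugs, and the criterion deteriorates
  steadily once the active set outgrows the supported model, so the scan
  stops after 10 consecutive distinct sets without a new minimum
  (`patience`, set to `Inf` for an exhaustive scan).  Candidates whose
  unpenalized refit fails (separation) are skipped with a warning; the
  intercept-only model is always a candidate.
* **Logistic fits.** All unpenalized fits use an in-package Newton
  iteration with step-halving; quasi-separated fits (any |slope| ≥ 30) are
  flagged and surface as `NA` rows that are excluded from the BH multiplier
  `m` with a reported count.
* **Variance for weighted fits.** The sandwich (robust) estimator with
  weights treated as fixed is the default; model-based variance is
  available via `variance = "model"`.  With very small weighted cells the
  HC0 sandwich is anticonservative — a reason, alongside fit stability,
  for the eligibility filter.
* **Degenerate inputs.** A constant PS is collinear with the intercept in
  the adjustment model and is dropped with a warning (the fit degrades to
  the univariate one); an empty CISL selection yields an intercept-only PS
  (constant at the drug's prevalence); zero cells in a 2x2 make the pair's
  row `NA` rather than halting a run.
* **Ranking ties.** Ranked-detection curves order by adjusted p-value
  (raw p-value, then descending estimate, as fallbacks), with ties broken
  by descending estimate then drug code, so curves are reproducible.
* **Decision rule.** `signal <=> p_fdr <= level`, the BH step-up rejection
  rule; the boundary case matters only when adjusted p-values tie the
  level exactly.

## The synthetic-data generator

Real reference analyses of this kind run against national databases and
curated reference sets that cannot be redistributed.  The generator
(`simConfig()` / `simulateReports()`) therefore emulates the structural
features that drive detector behaviour, with planted ground truth so that
sensitivity, specificity and FDR are measurable exactly:

* sparse binary exposures — per-drug marginal prevalence drawn uniformly
  from 2–6%;
* a rare composite outcome — baseline rate 5%, one AE column (screening
  one outcome against many drugs, as in a targeted reference-set
  comparison);
* co-prescription blocks — a latent Bernoulli episode indicator per report
  and block (probability 0.10); block drugs are reported with probability
  `pHigh` inside an episode and `(1 - rho) * p` outside, with `pHigh` set
  to preserve the marginal prevalence.  The default coupling `rho = 0.90`
  yields within-block pairwise exposure correlations around 0.3 — strong
  co-prescription, deliberately so (see below);
* 10 true signals with log odds ratios uniform in 0.7–1.5, and 10
  confounded nulls, each sharing a block with a true signal: their
  univariate log-OR is biased away from zero while their coefficient in
  the joint model is exactly zero.  This is the planted
  masking/confounding that separates the detector families;
* defaults of 20,000 reports and 200 drugs.

The coupling strength was fixed by design so that the planted confounding
is material: with weak correlation every detector trivially agrees and the
comparison degenerates.  At the defaults the univariate screen flags at
least one confounded null in essentially every draw, while the joint-model
and matching-weight routes almost never do — the qualitative ordering the
package is built to exhibit.

What the generator does **not** model: patient covariates (age, sex),
duplicate reports, reporting trends over time, multi-AE outcome
correlation, and the long-tailed drug frequency distribution of real
databases.  Passing tests on this generator therefore demonstrate the
statistical mechanics of the detectors — bias resolution, error control,
recovery — under a known truth, not performance on any particular national
database.

## Problem sizes used in the test suite

Simulation-backed checks run at sizes chosen to keep the full suite fast
on a single CPU while preserving the regime each check is about: FDR
calibration uses 25 null-only databases of 10,000 reports x 25 drugs
(below 10,000 reports the smallest eligible drugs have so few weighted
events that the HC0 sandwich inflates the null rejection rate — a
small-cell artefact worth knowing about, recorded above); confounding
resolution uses 20 seeded draws of 5,000 reports x 60 drugs; recovery of
planted signals uses 20,000 reports (the generator default) x 60 drugs
over 6 seeds; CISL recovery uses 10,000 reports x 40 drugs over 8 seeds.
The acceptance script (`scripts/acceptance.R`) runs the full default
conditions: 20,000 reports x 200 drugs.

## Known limitations

* CISL's decision is the selection itself — there is no p-value and no
  error-control guarantee.  Under a global null the drug with the largest
  in-sample marginal association defines the start of the penalty path and
  enters it stably across subsamples, so CISL typically selects a handful
  of null drugs where a test-based rule would stay silent; it also
  occasionally selects a null drug tightly co-prescribed with a true
  signal (about 10% of confounded nulls at the default coupling).  On
  databases with realistically rare drugs (prevalences near 0.1% rather
  than this generator's 2-6%) subsampling variability suppresses both
  effects and the method behaves conservatively.
* IPTW is left untrimmed by design — its instability under extreme scores
  is part of what the comparison measures; a weight cap can be imposed by
  the caller before `weightedAssociationTest` if trimming is wanted.
* hdPS scores depend on the outcome through the ranking, so they cannot be
  cached across AEs; the exact ranking variant used in published hdPS
  pipelines differs across implementations — here it is the Bross
  multiplicative-bias formula with a 0.1 continuity correction on the
  candidate-outcome table, with no recurrence/severity covariate expansion
  (the covariates are already single-level binary indicators).
* The one-sided testing direction is harm (`b > 0`); protective
  associations are never declared by any detector.
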