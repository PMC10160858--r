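---
title: "Calibrating verbal-autopsy CSMFs for CCVA misclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating verbal-autopsy CSMFs for CCVA misclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Two data sources are available. The *unpaired* (surveillance) dataset holds,
for each of $n$ deaths, one predicted broad cause per CCVA algorithm
$k = 1, \dots, K$ and nothing else. The *paired* (reference-standard)
dataset additionally holds a reference cause per death, determined from far
richer information (e.g. minimally invasive tissue sampling). The quantity
of interest is the population CSMF $p$, a point on the $C$-simplex over a
small list of broad causes ($C = 7$ for children 1–59 months, $C = 5$ for
neonates in the built-in lists).

The generative model the package fits:

* each unpaired death $d$ has a latent true cause
  $z_d \sim \mathrm{Categorical}(p)$;
* given $z_d = i$, algorithm $k$'s prediction follows row $i$ of its
  misclassification matrix, $a_{dk} \sim \mathrm{Categorical}(M^{(k)}_{i\cdot})$,
  conditionally independently across algorithms;
* each paired death with reference cause $b_m$ contributes
  $a_{mk} \sim \mathrm{Categorical}(M^{(k)}_{b_m\cdot})$ — paired data inform
  $M$ only, never $p$, so calibration does not depend on the cause
  composition of the reference deaths;
* priors: $p \sim \mathrm{Dirichlet}(\alpha_p)$ and each row of each
  $M^{(k)}$ an independent Dirichlet.

Marginalising $z$ shows the implied predicted-cause distribution is
$q = M^\top p$, the relation the deterministic `backsolve_csmf()` inverts
directly. The Bayesian model exists because the direct inverse is exact only
in trivial settings: with more causes and noisy $\widehat M$ it routinely
leaves the simplex, while the posterior cannot.

The exact prior and likelihood factorisation of the original calibration
software are not fully published; the model above is reconstructed from its
published description and is algebraically consistent with the back-solve
relation. Differences from the original prior are possible; the defaults
here are documented below and configurable.

### Sampler

Fitting is a data-augmented Gibbs sampler with conjugate updates:
$z_d$ from mass $\propto p_i \prod_k M^{(k)}[i, a_{dk}]$; $p$ from
$\mathrm{Dirichlet}(\alpha_p + \text{latent-cause counts})$; each $M^{(k)}$
row from its Dirichlet with paired cross-tab plus unpaired
$(z = i, a_k = j)$ counts added. Unpaired records sharing a prediction
pattern have identical conditionals, so the sampler draws latent-cause
*counts* per pattern from a multinomial — distributionally identical to
per-record sampling, with cost scaling in the number of distinct patterns
($\le C^K$) rather than deaths. Latent causes are initialised at the first
algorithm's predictions (a warm start near the data). With $K = 1$ this is
single-algorithm calibration; with $K > 1$ the ensemble.

## Parameters that matter

* `p_prior` (default 1, flat): Dirichlet concentration on the CSMF.
  Dimensionless; raise above 1 only to encode genuine prior information on
  the cause composition.
* `M_prior_diag` / `M_prior_offdiag` (defaults 5 / 0.5): row priors for
  each misclassification matrix, shrinking rows toward the identity so that
  reference causes with few paired deaths default toward "the algorithm is
  right" instead of toward uniform confusion. The total prior weight per row
  (5 + (C−1)·0.5 = 8 for C = 7) is deliberately small next to a typical
  paired row (tens of deaths). Set both to 1 for a flat row prior.
* `n_chains`, `n_iter`, `n_burnin` (defaults 4 × 10,000, burn-in 5,000):
  desk-scale runtimes with stable quantiles. The latent-cause augmentation
  mixes slowly when sensitivities are low, so check
  `convergence_diagnostics()` (split-chain scale reduction flagged above
  1.01, plus an initial-positive-sequence ESS) and lengthen runs rather than
  trusting a single short chain.
* `credible_level` (default 0.95): equal-tailed posterior intervals from
  empirical quantiles of the pooled post-burn-in draws.

## Model comparison

`compute_waic()` uses the standard variance form: lppd is the sum over
records of the log posterior-mean density (via log-sum-exp), the effective
parameter count is the sum of per-record variances of the log density, and
WAIC $= -2(\mathrm{lppd} - p_{\mathrm{waic}})$; both data sources
contribute records. The "uncalibrated" comparator is not pinned down by the
published description, so it is explicit and switchable:

* `"fixed_p"` (default): the same model with $p$ frozen at the raw CSMF
  point estimate (for ensembles, the equally weighted average of the
  per-algorithm raw CSMFs), $M$ still sampled. This operationalises "the
  raw CSMF is incompatible with the observed misclassification rates":
  if $M^\top p_{\mathrm{raw}}$ sits far from the observed prediction
  frequencies, the frozen model fits poorly.
* `"marginal"`: scores each unpaired prediction against that algorithm's
  raw predicted-cause distribution directly (no misclassification link).
  Because that distribution is the saturated fit to the unpaired
  predictions, this comparator is weak by construction and is provided only
  to make the contested choice visible.

## What the synthetic generator does and does not emulate

The real record-level datasets are not deposited, so `preset_scenario()`
states a synthetic world once:

* `two_cause_worked_example`: the textbook two-cause setting — truth
  (0.30, 0.70), sensitivities (0.95, 0.65) — at large samples (20,000
  unpaired; 2,000 paired per cause) so estimates approach the algebraic
  solution (0.53, 0.47) → (0.30, 0.70).
* `child_like`: 7 broad causes, 1,589 unpaired deaths and two algorithms —
  the post-exclusion child analysis scale. The true CSMF defaults to the
  published calibrated ensemble point estimates (malaria 0.27, other
  infections 0.36, diarrhea 0.19, …) and the two misclassification matrices
  are fixed hand-built tables patterned on the published estimates: low to
  moderate sensitivities (0.10 for severe malnutrition, 0.44 for malaria
  with heavy leakage to pneumonia, 28% of other-infection deaths
  mislabelled pneumonia by the expert-rule algorithm). 56 paired deaths per
  cause ≈ the 394 conclusive child reference deaths spread evenly.
* `neonate_like`: 5 causes, 632 unpaired deaths, 80 paired per cause
  (the conclusive neonatal reference records are several hundred after the
  site exclusions; 400 total is a realistic round figure), prematurity
  over-diagnosis by both algorithms (sensitivities 0.85 / 0.63 with 0.25–0.30
  of other rows leaking into prematurity).

Both age-group presets emulate the datasets *after* the complete-case
exclusion of inconclusive expert-algorithm diagnoses, so their inconclusive
rates are 0; `inconclusive_rate` exists to simulate the pre-exclusion state
(the study's child rate was 252/1841 ≈ 0.137, the neonatal 186/818 ≈ 0.227).
Paired records are generated with *fixed* per-reference-cause counts, not a
sampled cause mix, because calibration provably does not use that mix.

Not emulated: VA questionnaires and symptom vectors (the generator draws
predicted labels directly from $M$), site or regional heterogeneity in
misclassification, sampling weights, and — by default — correlation between
algorithms' errors. A `shared_confusion` option forces all algorithms to
copy one mis-draw with the given probability, as a stress test of the
conditional-independence assumption; no data exist to set its magnitude
realistically, so its default is 0 and any nonzero choice is arbitrary.
A green test on synthetic data therefore establishes that the estimators
and sampler recover the stated world, not that the model assumptions hold
for any real VA dataset.

## Numerical and design choices

* Cause labels are matched case-insensitively after whitespace trimming;
  canonical order is fixed by the cause list and used for every vector and
  matrix. Missing predictions are CSV empty cells or the literal `NA`.
* Empirical misclassification rows with zero paired deaths become uniform
  rows flagged by `row_counts = 0` (keeping downstream linear algebra
  defined) — the Bayesian module instead handles them through the prior.
* `backsolve_csmf()` refuses matrices with condition number above 1e8
  (configurable, deliberately conservative) and reports out-of-simplex
  solutions unclipped with `feasible = FALSE` rather than renormalising.
* CSMFs must sum to 1 within 1e-9; reporting rounds percentages to one
  decimal, computation never rounds.
* Causes with no evidence in either dataset are flagged: their posterior is
  prior-driven.
* The interval-coverage experiment in the test suite runs with the *flat*
  M-row prior: its ground-truth matrices are strongly non-identity, so the
  identity-shrinkage default would deliberately bias that experiment and
  coverage would measure prior misspecification rather than sampler
  correctness. Real sparse-data use keeps the shrinkage default.
* Test- and script-scale MCMC settings (1–2 chains, a few thousand
  iterations) are runtime compromises; tolerances in the tests are set for
  the Monte-Carlo error at those sizes.

## Known limitations

* Single-cause labels only: probabilistic (multi-cause) CCVA output and
  multi-cause reference causes are out of scope, as are sampling weights
  and covariate- or region-dependent CSMFs.
* The latent-cause augmentation mixes slowly when misclassification is
  heavy; effective sample sizes per 1,000 draws can be well under 100, and
  weakly identified coordinates (low-sensitivity causes) have wide, slowly
  converging intervals.
* The reconstruction of the original model's priors is a design choice;
  posterior numbers need not match the original software exactly even on
  identical data.
* With zero paired records for a cause, its misclassification row is
  identified only through the prior, and the calibrated CSMF for that cause
  should be read as prior-driven.
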