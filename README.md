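# vacalibrate

Correcting cause-specific mortality fractions (CSMFs) estimated from
computer-coded verbal autopsy (CCVA) for algorithm misclassification.

## The problem

In settings without routine medical certification of death, cause-of-death
information comes largely from verbal autopsies (VAs): structured postmortem
interviews coded to a probable cause by algorithms such as InSilicoVA or
EAVA. The raw CSMF for cause *j* — the share of VA records the algorithm
assigns to *j* — is biased whenever the algorithm misclassifies, which it
does for a large fraction of deaths. If a limited *paired* dataset exists in
which deaths have both a CCVA prediction and a reference-standard cause
(e.g. from minimally invasive tissue sampling, MITS), the algorithm's
misclassification rates can be estimated and the raw CSMF *calibrated*.

Writing **M** for the row-stochastic misclassification matrix
(M<sub>ij</sub> = P(predicted cause *j* | true cause *i*); the diagonal
holds the cause-specific sensitivities), **p** for the true CSMF and **q**
for the predicted-cause distribution, the three are linked by

&nbsp;&nbsp;&nbsp;&nbsp;**q** = **M**ᵀ **p**.

Calibration back-solves this relation. The direct linear solve is exact for
two causes but can produce fractions outside [0, 100]% with more causes, so
the package's core is a Bayesian latent-cause model fitted by a Gibbs
sampler: each unpaired death carries a latent true cause *z* ~
Categorical(**p**), each algorithm's prediction given *z = i* follows row
*i* of its **M**, paired deaths inform **M** directly, and Dirichlet priors
complete the model. With several algorithms the same latent cause drives
every algorithm's prediction (the ensemble), which automatically weights
the more accurate algorithms favourably. Calibrated and uncalibrated models
are compared by WAIC (lower is better) on the combined paired + unpaired
data.

The package is organised as an analysis workflow: every computation lives in
the package (`R/`), and the numbered drivers under `analysis/` run the
pipeline — simulate, raw estimates and misclassification matrices, Bayesian
calibration, WAIC comparison — writing tables under `results/`. Because the
underlying surveillance and MITS record-level datasets are not public, the
workflow runs on a synthetic generator whose presets emulate them (sample
sizes, cause spaces and misclassification structure), with known ground
truth.

## Worked example

Suppose a CCVA algorithm has sensitivity 95% for cause A and 65% for cause
B, and classifies 53% / 47% of surveillance deaths as A / B:

```r
library(vacalibrate)
causes <- cause_list(c("cause_a", "cause_b"))
M <- misclassification_matrix(
  matrix(c(0.95, 0.05,
           0.35, 0.65), 2, 2, byrow = TRUE), causes)
q <- csmf(c(0.53, 0.47), causes)
backsolve_csmf(q, M)$p
#> cause_a cause_b
#>     0.3     0.7
```

The raw 53% for cause A conceals that 35% of true cause-B deaths are
mislabelled A: the calibrated CSMF is 30% / 70%. The Bayesian route
reproduces this from individual-level data — simulating the same scenario
(20,000 unpaired deaths, 2,000 paired deaths per cause) and fitting the
calibration model:

```r
g <- generate(preset_scenario("two_cause_worked_example"))
fit <- run_calibration(g$unpaired, g$paired,
  config = calibration_config(n_chains = 2, n_iter = 4000,
                              n_burnin = 1000, seed = 1))
fit
#> Calibrated CSMF posterior (ccva; 6000 draws, 2 chains)
#>     cause  mean lower upper
#> 1 cause_a 0.312 0.287 0.336
#> 2 cause_b 0.688 0.664 0.713
```

The posterior mean sits within Monte-Carlo error of the algebraic solution,
with 95% credible intervals. `comsa_raw_csmfs()` exposes the published raw
prediction counts of the Mozambique COMSA analysis (1,589 child and 632
neonatal complete-case VA records) so the raw CSMF tables and the equally
weighted uncalibrated ensemble can be recomputed exactly; for example the
child ensemble malaria fraction is (303 + 134) / (2 × 1589) ≈ 14%.

## Acceptance script

`scripts/acceptance.R` recomputes the deterministic two-cause calibration
from scratch — building the sensitivity matrix, back-solving the observed
(53%, 47%) distribution — and writes the resulting calibrated percentages as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
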