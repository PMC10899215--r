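---
title: "Quantifying a repeated-exposure adverse outcome pathway: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a repeated-exposure adverse outcome pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qaopr)
```

## The problem

Most quantitative adverse outcome pathway (qAOP) models describe a single
exposure at increasing doses. Chronic toxicity does not work that way: the
apical outcome emerges only after repeated insults, and the repetition at
which chronic-phase biology first responds differs between donors of primary
cells. `qaopr` quantifies a hypothetical AOP built for exactly this setting.
The pathway (`canonical_aop()`) has a dose root, two molecular initiating
events, eight biomarkers and two key events forming the acute-phase module
(12 nodes that respond to every exposure), and a chronic-phase module of six
key events plus the adverse outcome (7 nodes elicited only after a
donor-specific number of exposure repetitions). All analyses run on a study
of four doses including an untreated control, eight donors, six exposure
repetitions and three replicates.

Because public datasets with this structure essentially do not exist, the
package's first-class component is a virtual-data generator that serves as
ground truth; every inferential layer is then exercised against it.

## The virtual-data generator

`generate_primary()` produces the mean fold change and its standard
deviation for every (donor, exposure, dose, node) cell:

* Controls anchor the scale: fold change exactly 1, standard deviation 0.
* Acute-phase means grow along the dose axis by increments
  `zeta_d ~ U(0, 1)` and along the exposure axis by `zeta_e ~ U(0, 0.2)`.
* Chronic-phase nodes behave identically but only from the donor's onset
  repetition (donors 2, 4, 6 at repetition 3; donors 1, 3, 5 at 4; donors 7
  and 8 never). Before onset, treated cells are unelicited noise
  `0.8 + 0.4 U(0, 1)`, a band that can never reach the 2-fold activation
  threshold.
* Spread follows the jump between adjacent dose means:
  `s(d+1) = (fbar(d) + z (fbar(d+1) - fbar(d))) / (4 + 6 z)`, fresh
  `z ~ U(0, 1)` per cell.

Two points were genuinely open and are settled as package policy:

* **Composition of the two recursions.** The dose and exposure recursions
  are each one-dimensional; applying both literally to every cell
  over-determines the grid. We draw the dose increments once per donor and
  node (shared across exposures) and add per-exposure lifts to every
  treated dose. This is the only composition under which the two stated
  monotonicities — strictly increasing in dose at fixed repetition,
  non-decreasing in repetition at fixed dose — hold exactly rather than on
  average. Cell-level draws remain fresh for standard deviations and
  pre-onset noise.
* **Severity.** The donor table grades chronic toxicity severe / moderate /
  weak, but the generating formulas are fully specified without a severity
  term, and grading the increments (for example 1 / 0.6 / 0.3) caps weak
  donors below the 2-fold activation threshold forever, which contradicts
  the downstream behavior the model family is meant to exhibit. The default
  therefore treats severity as descriptive of the onset pattern;
  `severity_scale` lets users impose an amplitude grading.

What the generator deliberately does **not** emulate: pharmacokinetics of
the inter-exposure interval, non-monotone (hormetic) dose responses,
feedback between chronic damage and acute signaling, assay-specific
measurement error, or missing cells. Tests passing against this generator
show that the inference machinery recovers the structure this generator
encodes — not that it would behave as well on real chronic-toxicity data,
where the acute/chronic separation is blurrier and residuals are not
lognormal.

## Resampling replicate-level data

Downstream models consume replicate averages, not the ground-truth means,
because a real experiment would too. For each treated cell,
`resample_replicates()`:

1. Moment-matches a multivariate lognormal: on the natural-log scale
   `mu = ln(fbar^2 / sqrt(fbar^2 + s^2))`, `o = ln(1 + s^2 / fbar^2)`, with
   off-diagonals `rho sqrt(o o')` from the per-exposure response-response
   correlation of the primary data (`estimate_rho()`; pooled over donor and
   dose cells by default, a donor-averaged variant behind a flag). An
   indefinite plug-in covariance is repaired by eigenvalue clipping at
   1e-10 with the diagonal rescaled back.
2. Draws `kappa = 100` training samples, regresses each node on its pathway
   parents within the cell, and carries the slope posterior across exposure
   repetitions with the conjugate Gaussian update (`bayes_update()`),
   starting from ordinary least squares and treating the current cell's OLS
   residual variance as known. The likelihood carries a separate intercept,
   which is re-anchored to the cell means rather than chained; chaining it
   drags post-onset chronic levels toward their pre-onset history and the
   replicate averages would no longer track the ground truth.
3. Draws `R = 3` replicates ancestrally from the posterior predictive,
   `N(b0 + x_pa' beta, sigma^2 + (x_pa - xbar)' V (x_pa - xbar))`, nodes
   under the dose root from their lognormal marginal, and exponentiates
   back to fold changes. Control cells are emitted as exactly 1.

`kappa` matters only weakly (posterior uncertainty enters the predictive as
`O(1/kappa)`); `R` matters a lot, since replicate averaging with `R = 3`
sets the measurement-noise floor for every downstream fit.

## Regression layer

`fit_dose_lmm()` fits `log10` fold change against dose with a donor random
intercept by maximum likelihood (so nested comparisons remain valid) and
reports the Nakagawa–Schielzeth conditional R2; response-response pairs pool
all exposures (`fit_rr_lmm()`, and a cubic polynomial `fit_rr_poly()` for
reference). Log10 is the package-wide modeling scale: the activation
threshold `Delta = log10 2` means a doubling, and all network fitting,
sampling and exceedance queries use the same scale.

## Static Gaussian Bayesian network per exposure

`fit_gbn()` fits each node by OLS on its pathway parents (dose as a
continuous root) to the pooled donor-and-dose slice of one exposure
repetition. `logic_sample()` draws doses uniformly over the design range and
propagates ancestrally; `activation_probability()` reports
`P(node > Delta | dose in [d ± eps])` with `eps` defaulting to 5% of the
dose range; `probability_surface()` and `vus()` (trapezoid rule) summarize
activation over a threshold-by-dose grid (21-point grids by default).
Defaults of 1e5 logic samples put the binomial standard error of a
mid-range probability near 0.002 before the dose window cuts the sample.
The dose distribution used for sampling is not dictated by anything in the
model; uniform over the tested range is the package's choice, and
activation claims are anchored at the highest tested dose, where
dose-response statements are conventionally benchmarked.

## Non-stationary dynamic Bayesian network

`fit_dbn()` links exposure repetitions: each node at exposure `e` is
linear-Gaussian in its pathway parents at `e - 1` (first-order Markov, no
within-slice edges, dose pooled or stratified, never a root). Coefficients
are slice-specific — non-stationarity is the point, since couplings
strengthen as the chronic module comes online. Chronic siblings are heavily
collinear, so slice regressions use ridge with the penalty selected by
exact leave-one-out cross-validation on a 50-point log grid spanning 1e-4
to 1e2 (closed-form leverage shortcut; predictors are not rescaled because
every variable is already a log10 fold change). At `lambda = 0` the fit is
exactly OLS, which the tests pin down.

`transition_probability()` estimates
`P(AO at e > Delta | KE at e - tau > Delta)` by forward simulation:
initial states are bootstrap rows of the empirical replicate means at
`e - tau` (preserving cross-node dependence), trajectories acquire
per-node Gaussian residual noise per slice, and the evidence — an
inequality — reduces likelihood weighting to 0/1 weights, i.e. rejection.
The lag `tau` must equal the node's graph distance to the adverse outcome
(1 for KE8, 2 for KE4–KE7, 3 for KE2 and KE3). Conditioning events with no
bootstrap mass (chronic nodes before any donor's onset) are reported as
missing rather than silently zero. Residual variance in the forward pass is
the per-slice estimate; a pooled estimate would understate the growing
spread of later slices.

One caveat the simulation makes visible: the slice residual absorbs
donor-to-donor heterogeneity (who is elicited, how strongly), and the
forward pass re-injects it as independent noise. Conditional exceedance
probabilities are therefore systematically a little lower than the raw
concordance of the empirical rows, and seed-to-seed spread is substantial
(standard deviation around 0.1 for the KE8-conditioned probability).

## Data-driven pruning

`lasso_prune()` asks which lagged edges the data actually support, slice by
slice: multi-parent nodes by lasso (`glmnet`, exact zeros from coordinate
descent) with the penalty chosen by leave-one-out cross-validation under
the one-standard-error rule — the standard parsimony choice when the goal
is to zero out uninformative regulators; the CV-minimum is available via
`rule = "min"` but keeps spurious parents at a known, substantial rate —
and single-parent nodes by the t-test of the OLS slope at p < 0.05. Edges
whose child instance can no longer reach the adverse outcome through kept
edges of later slices are then culled on the unrolled slice graph (the
culling is idempotent), and surviving parent sets are refit by ridge
(a relaxed-lasso refit, so reported probabilities do not inherit lasso
shrinkage). `pruned_transitions()` recomputes the transition table and
marks severed queries as conditionally independent instead of inventing a
number.

## Numerical conventions and degenerate inputs

* Activation threshold `Delta = log10 2 ~ 0.3010`; all thresholds and fold
  changes on the log10 scale.
* Control cells are point masses; they bypass the lognormal and the
  per-cell regressions.
* Residual-variance floors at 1e-12 guard divisions; predictive variances
  are clipped at 0.
* Rank-deficient node designs, zero-variance responses, empty dose windows
  and empty conditioning events raise classed errors (`qaop_rank_error`,
  `qaop_singular_error`, `qaop_empty_window_error`,
  `qaop_empty_conditioning_error`) rather than returning NaN.
* All simulation entry points take explicit seeds; `run_qaop()` derives
  per-stage seeds from one master seed and writes them, with file
  checksums, into its manifest.

## Problem sizes used by the test suite

The bundled tests run the full study design (8 donors, 4 doses, 6
exposures, 19 biology nodes) across ten seeds with 1e5 Monte-Carlo draws
per probability estimate — the same sizes the acceptance script uses — and
a tiny 2-donor, 2-dose, 3-exposure bundle on a 5-node pathway for the
fast unit layers. Headline probabilities are averaged over the ten seeds;
single-seed values scatter by roughly ±0.1 and should be read accordingly.

## Known limitations

* The canonical AOP edge list encodes one defensible wiring of the
  hypothetical pathway (MIE-mediated ligand production, a BM5→BM8 chain
  rather than a fan-out from KE1); alternatives are supplied via the graph
  JSON.
* The DBN conditions only on single-node inequality evidence; joint or
  soft evidence would need a different weighting scheme.
* Pruned models refit with ridge on kept parents; post-selection inference
  (p-values after lasso) is out of scope.
* With eight donors, dose-specific slice fits rest on eight rows; the
  package warns rather than refuses, matching how such data would be
  analyzed in practice.
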