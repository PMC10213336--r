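---
title: "Models and methods: depression epidemiology and symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: depression epidemiology and symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

`symptomnet` packages the two analytic layers of a cross-sectional
caregiver depression survey — classical epidemiology and a regularized
partial-correlation network over the nine PHQ-9 symptom items — together
with a simulator that generates cohorts with known ground truth. This
vignette explains the models, the defaults, and the choices made where
the methodology left room.

## Scoring and the depression flag

The four instruments are scored by plain summation: PHQ-9 total (0–27),
GAD-7 total (0–21), a single 0–10 fatigue rating, and global quality of
life as the **sum** of the two WHOQOL-BREF global items, giving a 2–10
scale. A respondent is flagged as having clinically relevant depression
when the PHQ-9 total is at least 5 (the screening cutoff; it is a
`cutoff` argument everywhere, not a constant). Validation is strict: an
out-of-range item is an error naming the row and column, and rows with
*any* missing scale item are dropped (complete-case) with the count
recorded — in a survey with near-complete participation this is the
simplest defensible policy, and the drop count is surfaced so users can
judge its bite.

## Epidemiological layer

* **Prevalence.** `prevalence_ci()` uses the Wald normal-approximation
  interval by default. For cohorts in the thousands with prevalence near
  one third the Wald and Wilson intervals agree to the reported decimal;
  Wilson is available via `method = "wilson"` for small samples.
* **Chi-square tests** are uncorrected Pearson statistics
  (`sum((O−E)²/E)`, df = (r−1)(c−1)). No Yates continuity correction is
  applied anywhere; recomputing published two-by-two statistics from
  their printed counts reproduces the uncorrected values, not the
  corrected ones.
* **t tests** use the pooled-variance form with df = n₁+n₂−2 (the
  convention matching printed degrees of freedom), available both from
  raw data and from mean/SD/n summaries.
* **Wilcoxon rank-sum** uses mid-ranks and the tie-corrected normal
  approximation without continuity correction and reports *Z*. At very
  small samples (n per group around 8) the approximation deviates from
  the exact permutation p-value by a few hundredths for mid-range
  p-values; it is accurate in the tails. For the cohort sizes this
  package targets (hundreds per group) the distinction is immaterial.
* **Logistic regression** (`fit_logistic()`) is a hand-rolled IRLS with
  step-halving, which keeps the log-likelihood trace monotone and
  exposes it for inspection. Non-convergence and (quasi-)separation are
  flagged, not silently returned. Wald CIs are `exp(β̂ ± z·SE)`.
  `depression_design()` codes the covariates the way such studies
  tabulate them: age continuous, female indicator, financial status
  poor vs fair/good, social-media use often vs less, diagnosis dummies
  against an "other" reference, compliance poor vs good.
* **ANCOVA** (`ancova_group_effect()`) fits `y ~ group + covariates` by
  least squares and tests the group term by its partial (Type-III) F.
  With no covariates this equals the squared pooled t exactly. The
  default covariate set for the QOL comparison is the logistic model's
  predictor list. Note that with covariates in the model the error df
  is n minus the number of fitted coefficients; a printed F(1, n) with
  the full n as denominator df is not reproducible and the standard df
  is reported instead.

## The symptom network model

The network is a Gaussian graphical model: nodes are items, edges are
partial correlations conditional on all other nodes. Estimation is in
three steps.

**Correlation input.** PHQ-9 items are 0–3 ordinal ratings, so by
default item pairs are correlated polychorically: thresholds from the
marginal cumulative proportions through the inverse normal CDF, then
the latent correlation maximizing the bivariate-normal likelihood of
the observed contingency table (a two-step estimator; the bivariate
normal CDF is computed by 32-node Gauss–Legendre quadrature of the
single-integral identity). Pairs involving a continuous variable fall
back to Pearson on scores (a polyserial approximation); `method =
"pearson"`/`"spearman"` treat all columns numerically. Pairwise
matrices need not be positive semidefinite; eigenvalues below 1e-6 are
clipped and the matrix renormalized to unit diagonal, with the repair
flagged in the result.

**Graphical lasso.** `glasso()` maximizes
`log det K − tr(SK) − λΣ_{i≠j}|K_ij|` by block coordinate descent with
inner lasso solves (compiled, RcppArmadillo). The diagonal is
unpenalized. Convergence is declared when the mean absolute
off-diagonal change of the covariance iterate falls below `tol` (default
1e-4) times the mean absolute off-diagonal of S; hitting `max_iter`
raises a typed error carrying the last iterate. The solver ascends the
dual `log det W` subject to a box constraint, and that merit is
returned per sweep when `trace = TRUE` — it is non-decreasing when the
inner solves are run to convergence.

**EBIC selection.** `ebic_glasso()` fits a warm-started path of 100
penalties, log-spaced from λ_max (the largest absolute off-diagonal
correlation, which yields an empty graph) down to 0.01·λ_max, and picks
the λ minimizing `−2L + E ln n + 4Eγ ln p` with `L` the penalized-fit
log-likelihood and E the number of nonzero upper-triangle precision
entries (entries below 1e-8 in magnitude are structural zeros). γ
defaults to 0.5, the canonical conservative choice. Edge counts should
grow as λ shrinks; because coordinate descent produces exact zeros, an
occasional one-edge wobble along a warm-started path is numerically
possible and is reported as a warning rather than an error so that
bootstrap replicates are not aborted.

A deliberate property of this estimator (shared with the standard
implementations that evaluate EBIC at the penalized estimate rather
than at a refitted MLE) is a tail of small false-positive edges: at
n around 2000 with 9 nodes, true edges are recovered essentially always,
but a few spurious partials of magnitude 0.01–0.03 typically survive
selection. Users who need hard sparsity guarantees should interpret
edges below ~0.05 with caution or confirm them with
`edge_bootstrap()`.

**Covariate adjustment.** `adjusted_network()` re-estimates the network
with covariates (by default anxiety total and fatigue) included as
additional nodes in one joint fit, then returns the symptom subgraph.
Covariates-as-nodes preserves the partial-correlation semantics of the
adjusted edges (each symptom–symptom edge is now conditioned on the
covariates as well); residualizing first would change the estimand and
is intentionally not the default.

**Centrality and flow.** Strength (`Σ_j |w_ij|`) is the only centrality
computed — the index such studies report — with ties broken by node
order for reproducibility. `flow_edges()` extracts and ranks the direct
edges of one target node (global QOL in the intended use), assigning
layers 0/1/2 (target / direct neighbors / rest); no indirect-path
layering is attempted, as that is a display concern.

## Stability and comparison machinery

* **Case-dropping bootstrap** (`case_drop_bootstrap()`): for each drop
  proportion q in 0.05…0.75 (step 0.05) and each of B replicates,
  re-estimate on a without-replacement subsample of ⌈n(1−q)⌉ rows and
  correlate subsample strengths with full-sample strengths. The
  **CS-coefficient** is the largest q at which at least 95% of
  replicates correlate at least 0.7 — the standard operationalization
  of "with 95% probability, correlation ≥ 0.7"; at least 0.25 is
  minimally acceptable and 0.5 preferred. 0.75 is the grid maximum, so
  a reported 0.75 is right-censored by construction. B defaults to
  1000 for production runs; the tests use far smaller B since they
  check mechanics, not precision.
* **Edge-accuracy bootstrap** (`edge_bootstrap()`): with-replacement
  resampling, per-edge means and 2.5/97.5 percentile intervals. When an
  edge appears in fewer than 2.5% of resamples the raw percentile
  bounds can exclude the tiny positive mean, so intervals are widened
  to always contain the mean.
* **Network comparison test** (`network_comparison_test()`): permutation
  test on two statistics — absolute global-strength difference and
  maximum absolute edge difference — with the null built by pooling
  rows and permuting labels at the original group sizes, and add-one
  p-values `(1 + #{perm ≥ obs})/(1 + n_perm)` that can never be 0.
  Because the permutation scheme is exact under exchangeability, its
  type-I error is nominal by construction; the test suite verifies this
  empirically at a reduced size.

All resampling procedures are bit-reproducible given their `seed`
argument, and the pipeline stamps every output with the config hash and
all seeds.

## What the simulator does and does not emulate

`generate_cohort()` draws latent symptom scores from a multivariate
normal whose precision matrix is the configured `truth_network`
(standardized to unit variances), adds shared anxiety and fatigue
latents with configurable loadings, and discretizes through fixed
thresholds — the probit measurement model under which the polychoric
estimator is consistent, which is precisely what makes parameter
recovery a meaningful test. GAD-7 items load on the anxiety latent;
depression status (the thresholded PHQ-9 total) shifts the QOL item
latents downward; demographics are drawn independently from realistic
marginals (40.1% male, 82.0% married, and so on, all configurable).

Default thresholds were calibrated once against the marginal profile of
a guardian survey — PHQ-9 ≥ 5 prevalence near one third, mean GAD-7
near 3, mean fatigue near 3, mean global QOL near 6.6 — and frozen; the
default truth network is likewise a fixed reference draw (9 nodes,
density 0.3, precision weights 0.3–0.5) so that the calibrated
prevalence does not drift with the sampling seed.

The simulator intentionally does **not** emulate: dependence between
demographics and symptoms (covariate effects on depression other than
anxiety/fatigue are absent, so logistic coefficients for demographics
have true value zero), item-specific measurement quirks
(differential thresholds are supported but not defaulted),
non-Gaussian copulas, or any longitudinal structure. Passing tests
therefore demonstrate correct recovery of the *assumed* generating
model, not robustness to violations of it.

## Numerical choices and degenerate inputs

* Polychoric optimization is bounded to |ρ| ≤ 0.999 with cell
  probabilities floored at 1e-300; a failed likelihood falls back to
  Spearman with a warning. A variable with a single observed category
  is an error.
* glasso is warm-started along the path from the previous solution;
  λ = 0 reduces to matrix inversion (validated against `solve()`), and
  λ ≥ λ_max yields the empty graph exactly.
* A degenerate depression split (no or all depressed, e.g. an
  impossible cutoff) skips the group-comparison stages with an explicit
  warning; the network stages still run.
* Rank-deficient designs are errors naming the aliased columns, both in
  the logistic fit and the ANCOVA.
* Strength ties are ranked by node order; the config hash is a plain
  rolling polynomial over the serialized config (provenance, not
  cryptography).

## Problem sizes used in validation

The test suite and the acceptance script validate on sizes chosen to
make Monte-Carlo conclusions meaningful while staying lightweight:
consistency checks at n = 10,000–50,000 for single estimates; edge
recovery on 20 cohorts of n = 2,000 (9 nodes, truth density 0.2,
precision weights 0.55–0.70, implying partial correlations of roughly
0.2–0.4); comparison-test calibration with 100 split-cohort runs of
n = 500 per group and 200 permutations; stability checks with B in the
tens. Production-scale runs (B = 1000 bootstraps, 1000 permutations)
use the same code paths through `analysis_config()`.

## Known limitations

* The CS-coefficient is right-censored at the 0.75 grid maximum.
* Penalized-EBIC selection admits small spurious edges (see above);
  specificity around 0.85–0.9 at n = 2000 is expected, not a bug.
* The polyserial fallback (Pearson on scores) slightly attenuates
  mixed ordinal–continuous edges.
* The Wilcoxon approximation is inaccurate for exact inference at very
  small n; no exact test is provided.
* Only strength centrality is implemented; no bridge or expected
  influence indices, no node-predictability measures, and no graphical
  rendering beyond the base-graphics `plot()` method.
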