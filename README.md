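# symptomnet

Depression-prevalence epidemiology and PHQ-9 symptom-network analysis for
cross-sectional caregiver surveys.

Surveys of caregivers of psychiatric inpatients typically collect the
PHQ-9 (nine depressive-symptom items, 0–3), the GAD-7 (seven anxiety
items, 0–3), a single 0–10 fatigue rating, the two global
quality-of-life items of the WHOQOL-BREF (1–5 each), and a set of
demographic and clinical covariates. `symptomnet` implements, as tested
reusable building blocks, the two analytic layers such studies report:

1. **Epidemiology.** Depression prevalence (PHQ-9 total ≥ 5) with a Wald
   interval `p ± z·√(p(1−p)/n)`; univariable group comparisons
   (uncorrected Pearson χ², pooled-variance Student *t* with
   df = n₁+n₂−2, Wilcoxon rank-sum *Z* via the tie-corrected normal
   approximation); multiple logistic regression by IRLS with Wald odds
   ratios `exp(β̂ ± 1.96·SE)`; and ANCOVA comparing global QOL between
   depressed and non-depressed respondents by the partial *F* of the
   group term.

2. **Symptom networks.** A Gaussian graphical model over the nine PHQ-9
   items: a polychoric correlation matrix (the items are ordinal
   manifestations of latent continua) is fed to the graphical lasso,
   which maximizes

   ```
   log det K − tr(SK) − λ Σ_{i≠j} |K_ij|
   ```

   over positive-definite precision matrices K, with λ selected on a
   100-point log-spaced path by the extended Bayesian information
   criterion `EBIC = −2L + E·ln n + 4·E·γ·ln p` (γ = 0.5). Edge weights
   are partial correlations `w_ij = −K_ij/√(K_ii·K_jj)`. On top of the
   fitted network: strength centrality `s_i = Σ_j |w_ij|`, the
   case-dropping stability bootstrap with the correlation-stability
   (CS) coefficient, a nonparametric edge-accuracy bootstrap, a
   covariate-adjusted re-estimation (anxiety and fatigue entering as
   extra nodes), a flow extraction of the edges linking global QOL to
   each symptom, and a permutation test comparing two groups' networks
   on global strength and maximum edge difference.

Because raw survey data of this kind are typically not shareable, the
package ships a latent-Gaussian threshold simulator
(`build_truth_network()`, `generate_cohort()`) that produces cohorts
with a *known* sparse partial-correlation structure and realistic
marginals, so every estimator can be validated against ground truth.

## Worked example

```r
library(symptomnet)

cohort <- generate_cohort(generator_config(n = 1101, seed = 17))
scored <- score_cohort(cohort)
scored
#> Scored survey cohort: 1101 respondents
#>   depressed (PHQ-9 >= 5): 363 (33.0%)
#>   mean PHQ-9 3.8, GAD-7 3.1, fatigue 3.2, global QOL 6.6

prevalence_ci(sum(scored$depressed), nrow(scored))$percent
#> estimate    lower    upper
#>     33.0     30.2     35.7

net <- ebic_glasso(scored[, paste0("phq9_", 1:9)])
net
#> EBIC-gLASSO partial-correlation network
#>   9 nodes, 28 edges (lambda = 0.0299, gamma = 0.50, EBIC = 9223.7)
#>   correlation input: polychoric, n = 1101

head(strength_centrality(net)[order(strength_centrality(net)$rank), ], 3)
#>     node  strength rank         z
#> 6 phq9_6 0.8333494    1 1.2152280
#> 1 phq9_1 0.7672318    2 0.8818562
#> 8 phq9_8 0.7203161    3 0.6453020
```

One third of the simulated guardians screen positive for clinically
relevant depression (the generator is calibrated to that rate); the
network's most central symptoms are the items whose latent ground-truth
rows happen to carry the most partial-correlation mass for this truth
draw. `case_drop_bootstrap()` + `cs_coefficient()` quantify how far the
centrality ordering survives subsampling, and
`run_full_analysis(analysis_config(...))` executes the whole battery —
descriptives, logistic model, ANCOVA, network, adjusted network, QOL
flow, stability, optional subgroup comparison — writing every table as
CSV/JSON with a provenance manifest.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/symptomnet.R generate --out cohort.csv --seed 7
Rscript inst/cli/symptomnet.R analyze --input cohort.csv --out results/ --boot 1000 --seed 17
```

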