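# panelfinder

Discovery and small-sample validation of transcriptomic biomarker panels.

## What this is for

Small clinical expression cohorts — think a handful of healthy controls, a
disease-control group, and a case group profiled on a ~20,000-feature
array — are where biomarker analyses most easily fool their authors:
penalized models separate anything, cross-validation leaks, and a single
resampling estimate of the AUC is meaningless. `panelfinder` packages the
full discovery-to-validation pattern for this regime:

* **Differential expression** — empirical-Bayes moderated t, exact
  Wilcoxon rank-sum (enumerated null for small groups), BH-FDR, and the
  `|log2FC| > 1 & p < 0.05` screen.
* **Enrichment** — preranked GSEA with the weighted KS-like running sum
  (ES/NES, random-set permutation null) and hypergeometric
  over-representation, on user-supplied GMT collections.
* **Co-expression modules** — soft-threshold scan against the scale-free
  criterion (R² ≥ 0.85), unsigned adjacency, topological overlap (TOM),
  average-linkage module detection, eigengenes, eigengene-based merging,
  and module–trait correlation.
* **Hub ranking** — eleven node centralities (Degree, MNC, DMNC, MCC,
  EPC, BottleNeck, EcCentricity, Closeness, Radiality, Betweenness,
  Stress) with a ≥ 3-method top-k consensus.
* **Panel selection** — L1-penalized logistic regression with stratified
  CV (λ_min / λ_1se panels) and a per-gene AUC > 0.9, adj. p < 0.003
  diagnostic gate.
* **Validation** — nested CV with inner Welch-t selection and
  Firth-penalized logistic regression (finite estimates under complete
  separation), and a safe stratified 0.632+ bootstrap of a PCA + ridge
  classifier with a matched stratified permutation null, empirical p and
  Cohen's d.
* **Synthetic data** — a seeded generator planting DE genes,
  latent-factor modules, probe multiplicity and interaction-graph hubs,
  so every stage is testable offline against known truth.

The core corrected statistic is the 0.632+ estimator on the error scale
(err = 1 − AUC, no-information rate γ = 0.5):

    R = (err_oob − err_app) / (γ − err_app),  clipped to [0, 1]
    w = 0.632 / (1 − 0.368 R)
    err_632+ = (1 − w) err_app + w min(err_oob, γ)

## Worked example

```r
library(panelfinder)

# a cohort with planted structure: groups 5/10/11, 4 truly
# discriminative genes at a 4-log2 shift in the case group
sim <- simulate_study(sim_config(
  n_genes = 300, n_de_genes = 4, effect_size_log2 = 4, noise_sd = 0.5,
  n_modules = 2, module_size = 40, module_de_shift = 2, seed = 7))
st <- sim$study
print(st)
#> expression_study: 300 features x 26 samples
#> groups: Healthy=5, MM=10, MM_ONJ=11

# exact rank test of one planted gene, cases vs healthy controls
g <- sim$truth_panel[1]
wilcoxon_rank_sum(st$matrix[g, st$groups == "MM_ONJ"],
                  st$matrix[g, st$groups == "Healthy"])[c("u_stat", "p_two_sided")]
#> $u_stat
#> [1] 55
#> $p_two_sided
#> [1] 0.0004578755

# U = n1*n2 = 55 is complete separation; 0.000458 = 2 / choose(16, 5),
# the smallest two-sided p attainable at these group sizes (prints 0.000458
# at 6 decimals).

# validate the planted panel with the safe stratified 0.632+ bootstrap
val <- boot632_validate(st, sim$truth_panel, "MM_ONJ", "Healthy",
                        B = 200, P = 200, seed = 7)
print(val)
#> 0.632+ bootstrap validation (MM_ONJ vs Healthy, panel of 4 genes)
#>   OOB AUC mean 1.000, median 1.000, 95% CI [1.000, 1.000]
#>   mean 0.632+ AUC 1.000; empirical p = 0.0050; Cohen's d = 4.95
```

The OOB median of 1.000 with an empirical p below 0.05 and a Cohen's d
of 4.95 is the signature of a genuinely separable panel; on label-permuted
data the same pipeline returns AUCs centered at chance (the tests verify
both regimes).

The discovery side runs end-to-end with `run_discovery()` (DEG screen →
modules → DEG ∩ trait-significant-module pool → LASSO panel + consensus
hubs) and `run_validation()`; a command-line wrapper lives at
`inst/cli/panelfinder.R` with `simulate`, `dex`, `modules`, `netrank`,
`select`, `validate` and `run-all` subcommands.

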