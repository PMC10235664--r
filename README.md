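# protnet

Weighted correlation network analysis of serum proteomic panels, built to
dissect depression heterogeneity: which *clusters* of correlated proteins
track major depressive disorder (MDD), and which individual depressive
symptoms drive those associations.

Single inflammatory or metabolic markers (CRP, leptin, insulin) tag the
hypothesised immuno-metabolic depression dimension poorly. `protnet`
instead detects modules of correlated analytes in an unsigned weighted
correlation network, summarises each module by its **eigenprotein**, and
relates modules to diagnosis and to individual symptom endorsement under
tiered covariate adjustment.

## The method

Given a subjects × analytes matrix (immunoassay panel with missingness and
detection-limit censoring) and a phenotype table (3-level diagnosis, 30
ordinal symptom items scored 0–3, covariates):

1. **Preprocess** — exclude analytes with > 30% missingness; impute
   censored cells at their detection limit and missing cells at the
   analyte median; Blom inverse-normal transform
   `Φ⁻¹((r − 3/8)/(n + 1/4))`.
2. **Network** — adjacency `a_ij = |r_ij|^β` (β = 4, unsigned);
   topological overlap `TOM_ij = (L_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`;
   average-linkage clustering of `1 − TOM` with adaptive shape-based
   branch pruning (minimum module size 5). Eigenprotein = first principal
   component of the module, mean 0 / SD 1; kME = analyte–eigenprotein
   correlation.
3. **Associate** — OLS contrasts with control as reference: each
   eigenprotein vs current MDD (Bonferroni × number of modules), then the
   selected module vs each symptom's high- and low-endorsement groups
   (items dichotomised at ≥ 2; Bonferroni × items × modules). Adjustment
   tiers: base (batch, site, sex, age, education) → lifestyle (+ chronic
   diseases, smoking, alcohol, physical activity) → BMI.
4. **Stability** — split the cohort into random halves (1621 → 811 + 810),
   re-transform and re-cluster each half, track the module best
   overlapping the reference, and report per-analyte inclusion
   frequencies over 2 × iterations clusterings.

A synthetic cohort generator (latent-factor protein blocks, ordered-logit
symptom items with planted module–symptom coupling, detection-limit
censoring, MCAR missingness) makes the whole pipeline testable without
clinical data; see the vignette for its assumptions.

## Worked example

```r
library(protnet)
report <- run_all(run_config(stability_iterations = 100, seed = 7,
                             out_dir = "protnet_demo"))
report$modules
#>   module size variance_explained mean_abs_within_cor
#> 1    EP1   24          0.2590025           0.2265217
#> 2    EP2   21          0.2717244           0.2347503
#> 3    EP3   13          0.2859093           0.2260146
#> 4    EP4   10          0.3033077           0.2253679
#> 5    EP5    7          0.3356549           0.2246041
#> 6    EP6    6          0.3429478           0.2110667
report$status_scan[, c("module", "estimate", "p", "p_bonferroni", "selected")]
#>   module     estimate           p p_bonferroni selected
#> 1    EP1 -0.002362216 0.969590980   1.00000000    FALSE
#> 2    EP2  0.179834382 0.003754536   0.02252721     TRUE
#> 3    EP3 -0.026469552 0.669000246   1.00000000    FALSE
#> 4    EP4 -0.052416561 0.397095396   1.00000000    FALSE
#> 5    EP5 -0.001565438 0.979735585   1.00000000    FALSE
#> 6    EP6  0.041114102 0.507497364   1.00000000    FALSE
```

Six modules are detected on the default 171-analyte synthetic panel (90
analytes unassigned). The second module — 21 analytes, 4 of them
negatively loaded, mean within-module |r| ≈ 0.23 — is elevated in current
MDD (here p = 3.8e-3, Bonferroni-adjusted 0.023) and is selected for the
symptom scans, where exactly the five planted "energy-related" items are
Bonferroni-significant in the high-endorsement contrast
(`report$symptoms_high`) and none in the low-endorsement contrast. The
split-half analysis (`report$stability`) reports the mean size of the
best-overlapping module, its mean overlap with the reference, and
per-analyte inclusion frequencies.

A command-line wrapper exposes each stage
(`simulate | preprocess | network | associate | stability | run-all`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/protnet.R", package="protnet"))')" \
  run-all --out demo_run --seed 7
```

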