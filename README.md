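# ryegs

Genomic selection and marker-assisted selection in hybrid rye testcross
populations: simulation, two-stage REML phenotypic analysis, RR-BLUP and
CIM-based prediction, and a full taxonomy of cross-validation schemes.

## What this package is for

Hybrid rye breeders evaluate F3:4 line candidates through testcrosses to a
CMS tester grown in multi-location, multi-year trials. Two marker-based
shortcuts compete with full phenotyping: **genomic selection** (GS), which
predicts a candidate's testcross value from all markers jointly via
ridge-regression BLUP, and **marker-assisted selection** (MAS), which uses a
few QTL mapped by composite interval mapping. `ryegs` provides the complete
analysis chain for comparing them in two half-sib bi-parental populations
(220 F3:4 lines each, sharing one parent), including a calibrated simulator
of the trial system, so that every estimator and every cross-validation
scheme is testable without access to proprietary field data.

The statistical core:

- Stage 1 (per environment): `y = μ1 + G α_G + R α_R + B α_B + e`, genotype
  fixed, replication and block random → per-environment BLUEs and
  repeatability `r = σ²_g / (σ²_g + σ²_e/n_rep)`.
- Stage 2 (across environments): `y = μ1 + G α_G + E α_Env + F α_F + e` →
  across-environment BLUEs (genotype fixed) or variance components
  (genotype random), with heritability
  `h² = σ²_G / (σ²_G + σ²_GE/n_Env + σ²_e/(n_Env·n_Rep))`
  and interaction ratio `σ²_GE / (σ²_G + σ²_GE)`.
- RR-BLUP: solve `[[1'1, 1'X], [X'1, X'X + λI]] [μ̂, â]' = [1'y, X'y]'` with
  `λ = m(1−h²)/h²`, predict `ĝ = μ̂ + X_new â`; equivalent to GBLUP with
  `K = X_c X_c'`.
- CIM: forward-stepwise cofactors, 1-cM scan with a 10-cM cofactor exclusion
  window, `LOD = (n/2)·log10(RSS_reduced/RSS_full)`, detection at LOD ≥ 3.73.
- Cross-validation: 5-fold genotype sampling within/across populations,
  environment-count sampling (1–9), and location/year transfer schemes, with
  accuracy `r_p` (Pearson) and standardized accuracy `r_g = r_p/√h²`.

## Worked example

```r
library(ryegs)

parents <- simulate_parents(n_markers_per_chrom = 20, seed = 1)
popA <- simulate_f3_population(parents, "A", n_lines = 100, seed = 2)
popB <- simulate_f3_population(parents, "B", n_lines = 100, seed = 3)
trial <- simulate_trial(popA, popB,
                        trait_architecture("grain_yield", n_qtl = 30),
                        seed = 4)
markers <- impute_missing(filter_markers(combine_populations(popA, popB))$markers)

s1 <- step1_blues(trial)          # per-environment BLUEs + repeatability
vc <- step2_fit(s1, "random")     # variance components across environments
vc
#> Variance components (two-step): s2_G = 3.09, s2_GE = 9.208, s2_e = 3.527
#> h2 = 0.717 over 9 environments x 2 reps
round(ge_ratio(vc), 2)
#> [1] 0.75

gd <- prepare_gs_data(trial, markers, blues = s1)
cv <- run_cv_population(gd, "within_within_same", predictor = "rrblup",
                        population = "A", n_resamples = 100, seed = 5)
summary(cv)
#> CV scheme within_within_same / predictor rrblup: 100 replicates (0 degenerate excluded)
#>     median    q1    q3  mean    sd
#> r_p  0.833 0.767 0.873 0.817 0.073
#> r_g  1.021 0.932 1.073 0.998 0.101
```

The simulated grain-yield trial recovers variance components close to its
calibration targets (genotypic variance 3.33, interaction 8.40, error 3.48);
the interaction ratio 0.75 says that three quarters of the genetic-plus-
interaction variance is environment-specific, which is what limits accuracy
when predictions must transfer to new locations or years. The within-
population 5-fold accuracy `r_p ≈ 0.83` is the ceiling scenario: estimation
and test sets are full sibs evaluated in the same nine environments.
`run_cv_env()` and `run_cv_location_year()` quantify how much of that
accuracy survives fewer environments or transfer across locations and years,
and `predictor = "mas_qtl"` or `"mas_neut"` swaps in the MAS baselines.

A single-command end-to-end run (simulate → QC → BLUE → variance components
→ CV, with all artifacts written as plain text plus a JSON manifest):

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "ryegs"),
             out_dir = "demo_run")
```

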