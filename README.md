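# dvcforest

Causal-forest derivation of mandible dose-volume constraints (DVCs) for
osteoradionecrosis (ORN), and empirical proton RBE from paired
photon/proton tolerance curves.

## What it does, and for whom

Head-and-neck radiotherapy cohorts treated with photon VMAT or
pencil-beam-scanning proton therapy (PBSPT) record which patients developed
mandible ORN, their clinical risk factors, and their mandible dose-volume
histogram (DVH) indices (V40/V50/V60/V70 Gy in cc, Dmax/Dmean in cGy).
Outcomes researchers who want constraint tables from such data face a
causal problem: dose is confounded with tumour stage, dental history and
smoking, which also drive ORN. `dvcforest` provides the full analysis chain
for that setting:

1. **Matching** — logistic propensity scores and *exactly optimal* 1:1
   matching between modality groups (order-preserving dynamic program on
   the sorted logit scores), with chi-square / t-test balance tables before
   and after.
2. **Within-group balance** — worst-case standardized mean differences of
   each clinical factor across quartile strata of each dosimetric factor,
   `SMD_max = max_{i≠j} |μ_i − μ_j| / √((σ_i² + σ_j²)/2)`, flagged at the
   0.2 / 0.8 conventions, with a three-band heatmap.
3. **Honest causal forest** (Rcpp) — subsampled honest trees whose splits
   maximize treatment-effect heterogeneity, local centering via
   regression-forest residuals, out-of-bag CATEs, and a doubly-robust AIPW
   estimate of `ATE = E[Y(T=1) − Y(T=0)]` (a risk difference) with
   influence-function standard errors.
4. **DVC derivation** — for each dosimetric factor, scan binarization
   thresholds `T = 1[V > v]` over the 1st–99th empirical percentiles, fit
   the forest at each cutoff, select the threshold with the most
   significant ATE (largest `ate/se`; plain ATE argmax available) as the
   critical constraint, and bootstrap the whole scan for percentile CIs;
   plus a randomized-dosimetry robustness check (uniform pseudo-dose must
   yield ATE ≈ 0).
5. **Empirical RBE** — the VxGy critical volumes form per-modality volume
   tolerance curves; for a nominal proton dose `d` Gy[RBE=1.1] (physical
   dose `d/1.1`), linear interpolation of the photon curve at the proton
   critical volume gives the equivalent constraint dose `d_γ`, and
   `RBE = d_γ / (d / 1.1)`, with bootstrap CIs.
6. **Synthetic cohorts** — a seeded generator with registry-style covariate
   marginals, confounded modality and dose assignment, structural
   missingness (`MISSING` is a modelled category, never imputed), monotone
   per-patient VxGy, and a configurable ground-truth threshold effect, so
   the whole pipeline is testable without patient data.

Everything is tibble-in / tibble-out and pipe-friendly, with
`tidy()`/`glance()` methods and `autoplot()`s for the result types.

## Worked example

```r
library(dvcforest)

# an imbalanced two-modality cohort with known structure
cohort  <- simulate_cohort(
  sim_config(n_per_modality = c(VMAT = 900, PBSPT = 300)), seed = 1)

matched <- match_cohorts(cohort)
matched
#> Matched cohort: 300 pairs; total propensity distance 30.37
tidy(matched)
#> # A tibble: 9 × 3
#>   covariate         p_before p_after
#>   <chr>                <dbl>   <dbl>
#> 1 age               1.67e- 4   0.951
#> 2 tumor_stage       1.36e- 8   0.216
#> 3 gender            4.81e- 4   0.829
#> 4 chemo             3.95e-19   0.969
#> 5 smoking_history   5.37e-22   0.877
#> 6 current_smoker    6.45e-20   0.954
#> 7 hypertension      4.65e-20   0.637
#> 8 diabetes          5.62e-19   0.966
#> 9 dental_extraction 5.64e-19   0.947
```

Every covariate is sharply imbalanced before matching (p < 0.001 for most)
and balanced after (all p > 0.05) — the matched cohort is fit for the
causal analysis. The effect of exceeding a dose-volume cutoff:

```r
tv <- binarize(matched$matched, "V60Gy", 40)   # 1[V60Gy > 40 cc]
cf <- causal_forest(matched$matched, tv, n_trees = 500, seed = 1)
estimate_ate(cf)
#> # A tibble: 1 × 7
#>      ate     se   ci_lo  ci_hi n_treated n_control method
#>    <dbl>  <dbl>   <dbl>  <dbl>     <int>     <int> <chr>
#> 1 0.0290 0.0203 -0.0107 0.0688       175       425 aipw
```

Exceeding 40 cc at V60Gy raises ORN risk by an estimated 2.9 percentage
points in this synthetic cohort (CI crossing zero at this cohort size).
`scan_thresholds()` + `derive_dvc()` repeat this over the percentile grid
and pick the critical volume; `derive_dvc_table()` does all six factors
with bootstrap CIs, and `run_dvc_pipeline()` runs the whole chain and
writes the artifact bundle.

The RBE arithmetic, given equivalent photon constraint doses of
58.58 / 59.10 / 61.75 Gy at nominal proton doses 40 / 50 / 60 Gy[RBE=1.1]:

```r
empirical_rbe(c(58.58, 59.10, 61.75), c(40, 50, 60))
#> [1] 1.610950 1.300200 1.132083
```

i.e. outcome-equivalent photon doses imply proton RBE well above the
planning constant 1.1 at moderate doses, falling toward it by 60 Gy.

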