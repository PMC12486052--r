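---
title: "Deriving dose-volume constraints and empirical proton RBE with causal forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving dose-volume constraints and empirical proton RBE with causal forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mandible osteoradionecrosis (ORN) is a severe late toxicity of head-and-neck
radiotherapy. Observational cohorts treated with photon VMAT and
pencil-beam-scanning proton therapy (PBSPT) make it possible to ask two
clinically consequential questions:

1. At each dose level, what mandible volume can safely receive that dose —
   i.e. what is the critical dose-volume constraint (DVC)?
2. When the photon and proton constraint curves disagree, what proton
   relative biological effectiveness (RBE) do the patient outcomes imply,
   compared with the planning assumption of a constant RBE = 1.1?

Answering these from real-world data is a causal problem, not a predictive
one. Which patients receive high mandible doses is driven by tumour stage,
dental status, smoking and other clinical factors that also modify ORN risk,
so a regression or machine-learning association between dose and ORN mixes
the dose effect with confounding. `dvcforest` implements the full analysis
as a causal-inference pipeline: propensity matching between modalities,
worst-case standardized-mean-difference (SMD) diagnostics of the residual
confounding *within* each modality, an honest causal forest that estimates
the effect of exceeding a dose-volume threshold, an ATE-maximizing threshold
scan that derives the DVCs, and equivalent-constraint-dose interpolation
that turns paired photon/proton tolerance curves into empirical RBE values.

Because institutional patient records cannot be redistributed, the package
ships a seeded synthetic cohort generator with the same statistical
structure, and every stage is tested against it.

## Estimand

For a dosimetric factor $V$ (say V60Gy, the mandible volume in cc receiving
at least 60 Gy) and a cutoff $v$, the exposure is $T = \mathbf{1}[V > v]$
(ties count as unexposed, so the grid scan is deterministic), the outcome
$Y \in \{0, 1\}$ is ORN, and the estimand is the average treatment effect

$$\mathrm{ATE}(v) = E[Y(T = 1) - Y(T = 0)],$$

a risk difference because $Y$ is binary. The critical DVC is the cutoff
whose ATE is *most significant*: the default rule maximizes
$\widehat{\mathrm{ATE}}/\widehat{\mathrm{se}}$ over the grid
(`rule = "max_z"`), with the plain ATE argmax available as
`rule = "max_ate"` and ties resolved to the smallest threshold. The z-rule
is the default on statistical grounds: the scan grid is strongly
heteroscedastic (near the grid edges one arm shrinks toward the `min_arm`
floor and the ATE standard error inflates severalfold), and an argmax over
heteroscedastic estimates is systematically attracted to the noisiest
points. In step-effect simulations the plain argmax throws a visible
minority of derived constraints to the extreme percentiles, while the
z-rule localizes the true cutoff; the package therefore treats "largest
causal effect" as largest standardized effect.

## The honest causal forest

The forest is written for this package (Rcpp core) rather than wrapped from
an existing library, and follows the generalized-random-forest recipe in a
deliberately compact form:

* **Subsampling.** Each of `n_trees` (default 2000) trees is grown on a
  fraction (default 0.5) of the cohort drawn *without* replacement.
* **Honesty.** Each subsample is split in half: a *structure* half that
  alone decides the splits, and an *estimation* half that alone supplies
  the leaf effects. Permuting estimation-half outcomes therefore changes
  leaf estimates but can never change tree shape — an invariant the test
  suite asserts directly.
* **Split rule.** Every candidate cut on every sampled covariate (`mtry`
  defaults to $\min(\lceil\sqrt p\rceil + 20, p)$) is scored by
  $\frac{n_L n_R}{n_P^2}(\hat\tau_L - \hat\tau_R)^2$, the size-weighted
  squared difference of the child effect estimates — maximizing treatment-
  effect heterogeneity across children. The within-node effect estimate is
  $\widehat{\mathrm{cov}}(W, Y)/\widehat{\mathrm{var}}(W)$, which reduces to
  the treated-minus-control mean difference for a raw binary treatment.
  Score ties resolve to the first covariate in schema order, then the
  lowest cut, so fits are bit-reproducible.
* **`min_leaf`** (default 5) counts treated and control samples separately
  in the estimation half (and the structure half) of every prospective
  child, so each leaf effect is always defined.
* **Local centering.** By default the forest is fit on residuals
  $Y - \hat m(X)$ and $T - \hat e(X)$, with $\hat m, \hat e$ out-of-bag
  predictions from `ranger` regression forests. This orthogonalization is
  what gives the forest its robustness to observed confounding; it is the
  recommended default. `centering = "parametric"` (linear model for $Y$,
  logistic for $T$) is an order of magnitude faster and is what the heavily
  replicated bootstrap simulations in the test suite use;
  `centering = "none"` exists for ablation and for hand-checkable splits.
* **OOB CATE and AIPW ATE.** Each patient's conditional effect
  $\hat\tau(x_i)$ averages the leaf effects of the trees whose subsample
  excluded patient $i$. The ATE is the mean of the doubly-robust AIPW
  scores
  $\hat\tau(x_i) + \frac{T_i - \hat e_i}{\hat e_i(1-\hat e_i)}
  \left(Y_i - \hat m_i - (T_i - \hat e_i)\hat\tau(x_i)\right)$,
  with standard error the score standard deviation over $\sqrt n$
  (an influence-function estimate; its simulation coverage is tested).
  A plain mean of OOB CATEs is available as a cross-check estimator. If
  $\hat e$ leaves $[0.01, 0.99]$ for more than 5% of patients the estimate
  carries a positivity warning.

## Matching and balance diagnostics

Between-modality balance uses textbook propensity matching: a maximum-
likelihood logistic model of $P(\mathrm{PBSPT}\mid X)$ on one-hot covariates
(age linear), a ridge fallback ($\lambda = 10^{-6}$) under near-separation,
and globally optimal 1:1 matching. Because the matching distance is the
absolute difference of a *scalar* (the logit propensity, common PSM
practice; raw scores via `distance = "raw"`), the optimal assignment never
crosses pairs, so the package solves it exactly with an order-preserving
dynamic program over the two sorted score vectors — $O(nm)$ and provably
optimal, which the test suite confirms against brute-force enumeration of
all assignments on small instances. No caliper is applied by default, so
the pair count equals the smaller group.

Within-group balance is the worst-case SMD: stratify each modality group
into quartiles (low / mid-low / mid-high / high) of a dosimetric factor —
quartile ties fall in the lower stratum so heavily tied volumes (e.g. many
V70Gy zeros) stratify deterministically — and take

$$\mathrm{SMD}_{\max} = \max_{i \ne j}
\frac{|\mu_i - \mu_j|}{\sqrt{(\sigma_i^2 + \sigma_j^2)/2}}$$

over the six stratum pairs, and additionally over levels for categorical
factors (each level as a 0/1 indicator; the worst case throughout).
Cells classify as balanced ($< 0.2$), moderately biased ($[0.2, 0.8)$) or
highly biased ($\ge 0.8$), intervals closed on the left; a zero-variance
pair with unequal means renders as a distinct degenerate flag rather than a
number. This diagnostic is what motivates the causal forest: 1:1 matching
equalizes the two modality groups but does nothing about confounding of
dose *within* a group.

## Threshold scan, bootstrap, robustness

`scan_thresholds()` walks the 1st–99th percentiles of a factor's empirical
distribution in 1-percentile steps (the "1% increments" are percentile
steps, not steps of the raw range: this keeps both arms populated at every
grid point and matches the normalized-factor convention of the robustness
check; a raw grid can be supplied via `grid`). Thresholds leaving fewer
than `min_arm = 10` patients in an arm are skipped and logged. Each modality
is scanned separately with clinical covariates (only) as forest features.

`bootstrap_dvc()` resamples patients with replacement and reruns the
*entire* scan-plus-selection per replicate, so the percentile CI reflects
threshold-selection variability rather than ATE noise at a fixed cutoff.
Per-replicate seeds derive deterministically from the master seed, so runs
are reproducible and parallelizable in principle.

`robustness_check()` replaces each dosimetric factor in turn with iid
Uniform(0,1) draws, binarizes at the median, and refits the forest: any
systematic deviation of these null ATEs from zero would indicate the
pipeline manufactures effects. On the default 670-patient synthetic cohort
the maximum |ATE| stays within 0.02.

## Tolerance curves and empirical RBE

The VxGy critical volumes at 40/50/60/70 Gy form a per-modality volume
tolerance curve. For a nominal proton dose $d$ (in Gy[RBE=1.1], i.e.
physical dose $d/1.1$), the proton critical volume is read off the proton
curve and the *equivalent constraint dose* $d_\gamma$ is the photon dose at
which linear interpolation of the photon curve attains that same volume.
The empirical RBE is

$$\mathrm{RBE}(d) = \frac{d_\gamma}{d / 1.1}.$$

Interpolation is linear in (dose, volume) space with no smoothing; queries
outside the photon curve's volume range refuse to extrapolate, and on a
non-monotone curve the lowest matching dose is returned with a warning.
Bootstrap replicates of both curves propagate into percentile CIs for the
RBE; replicates that would extrapolate are dropped and counted, and a CI
with more than 20% drops is flagged unreliable. Four tolerance-curve knots
are a coarse grid, so interpolated equivalent doses inherit that
resolution; supplying DVCs at a finer set of dose levels sharpens them.

## The synthetic cohort generator

`sim_config()` encodes the study conditions the analysis is designed for:

* **Covariates** follow registry-style marginals for a photon/proton
  head-and-neck population — 74% male, age centred near 62, stage IV in
  about half, and modality-specific shifts (proton patients older, fewer
  smokers, less stage IV). `confounding_modality` blends these
  modality-specific marginals toward the pooled ones; at 0 the arms are
  exchangeable, which the chi-square null test exploits.
* **Missingness** is structural, not random: a per-patient site indicator
  (different mix per modality) blanks the six history fields collected at
  one campus only. Missing values become the category `"MISSING"` and are
  never imputed.
* **Dosimetry** comes from a latent per-patient dose-burden scalar (shared
  correlation 0.8 across factors) plus factor noise, with per-modality
  means and SDs loosely centred on the clinical scale of mandible DVH
  indices; VxGy values are sorted per patient so cumulative-DVH
  monotonicity holds by construction, and Dmax ≥ Dmean is enforced.
  Clinical factors (stage IV, dental extraction, current smoking) shift the
  burden via `confounding_dose` — that is the within-group confounding the
  forest must remove.
* **Outcome** follows
  $\mathrm{logit}\,P(Y{=}1) = \alpha + \beta^\top x + \gamma\,
  \mathbf{1}[V > v^*]$, with an identity-link variant whose $\gamma$ *is*
  the risk difference (used whenever a test needs an exact ground truth).
  The default base rate 0.01 puts the marginal ORN prevalence near 2.8%,
  the registry scale; power-hungry tests raise it to 6–15% explicitly.
* `ground_truth_ate()` computes the implied estimand for any factor and
  threshold by Monte Carlo, treating intervention on $T$ as a redraw of the
  factor from its modality-conditional distribution truncated above/below
  the cutoff; at $v^*$ this collapses to the configured effect.

What the generator does *not* emulate: spatial dose distributions and LET,
time-to-event structure (ORN is a late effect; here it is a fixed binary),
correlated missingness beyond the site pattern, inter-centre protocol
drift, and any dependence between patients. Passing tests demonstrate that
the estimators recover known effects under this structure — not that any
particular clinical dataset satisfies it.

## Numerical and design choices

* Doses are stored in cGy internally (`Dmax`, `Dmean`); file input may be
  Gy with `dose_unit = "Gy"`. Volumes are absolute cc.
* Binarization sends ties to control ($T = \mathbf{1}[V > v]$), making the
  percentile grid scan deterministic.
* One-hot level order is alphabetical with `MISSING` last — design matrices
  are identical across runs.
* The split-score tie-break (first covariate, lowest cut), the estimation
  eps on within-node variance ($10^{-12}$), the propensity clamp
  $[0.01, 0.99]$ in the AIPW score, and the seed fan-out
  $(48271 s + 1009 k) \bmod (2^{31}{-}1)$ are all fixed constants, chosen
  once for determinism rather than tuned.
* A single-leaf tree is a valid degenerate fit (its estimate is the
  subsample's honest overall effect), not an error; a constant treatment,
  a constant scanned factor, or an empty modality group is an error.

Simulation-based tests use deliberately scaled problem sizes — cohorts of
500–4000 patients, forests of 25–300 trees, bootstrap of 100 replicates at
a coarsened percentile grid — chosen so the whole suite exercises every
claim at useful power while staying quick to run; the full-size defaults
(2000 trees, 1% grid, 1000 bootstrap iterations) are exercised where single
fits suffice, as in the robustness check.

## Limitations

* The forest implements the core GRF recipe (honest subsampled trees,
  heterogeneity splits, local centering, AIPW) but not gradient-based
  pseudo-outcome splitting, bootstrap-of-little-bags standard errors,
  clustered sampling, or variable importance.
* DVCs are derived per dosimetric factor with no multiplicity adjustment
  across factors, mirroring standard practice for constraint tables.
* Equivalent doses interpolate between whatever dose levels the tolerance
  curves contain; conclusions at doses outside the photon curve's volume
  range are deliberately unavailable rather than extrapolated.
* The estimand at thresholds away from a true step (if one exists) is a
  stochastic-intervention contrast; its ground-truth definition is part of
  the generator, and other intervention conventions would give different
  off-threshold curves.
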