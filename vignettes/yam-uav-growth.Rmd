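---
title: "Methods: synthetic UAV phenotyping and hierarchical growth modeling for staked yam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic UAV phenotyping and hierarchical growth modeling for staked yam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(yamphen)
```

This vignette documents the models behind `yamphen`, the parameters that
matter, and the design decisions taken where several defensible options
existed. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## 1. What the simulator emulates, and what it does not

The pipeline targets trials on single-staked white Guinea yam in which
per-plant shoot biomass is estimated from multi-view UAV imagery and
genotype growth dynamics are summarized by fitted curves. Because the
original field data are not publicly deposited, the package ships a
synthetic-data module whose defaults reproduce the trial *design*:

* a split-plot RCBD with fertilizer on main plots and genotype on
  subplots: 12 genotypes x 2 treatments x 3 blocks = 72 plots per year,
  3 x 3 m plots at 1 x 1 m spacing (16 plants on the fence-post grid),
  4 plants destructively sampled per plot at 2 stages in 2 years
  (1,152 plants);
* a monitoring trial of 12 genotypes x 8 plants x 3 replicates observed
  at 11 flights (3,168 records).

**Flight schedule.** The default series times are `seq(14, 224, by = 21)`
days after transplanting (DAP): first flight two weeks after
transplanting, then every three weeks into late season. The schedule
must extend past senescence onset (`t_d` around 190–200 DAP, matching
the onset of the dry season) for the decay parameters to be informed by
data at all; a schedule ending at canopy peak would leave `d` and `t_d`
prior-driven. The out-of-range warning for series time points is set at
[0, 250] DAP accordingly.

**Canopy geometry.** Staked yams form columnar canopies. Each plant is a
cylinder–cone blend: surface height at distance `rho` from the stem is
`h (b + (1-b)(1 - rho/r))`, with one architecture coefficient
`b in [0,1]` (1 = cylinder) and a leaf-cover fraction that thins the
footprint. A constant 0.40 m ridge lifts the ground inside the patch;
within-patch ridge tilt adds nothing testable and is omitted.

**View model.** Photogrammetric surface models flatten tall thin
canopies, more so from a single view than from a combined
oblique-plus-nadir reconstruction. Two mechanisms, both per view set:
an additive height bias (means −0.25 / −0.35 / −0.10 m for oblique,
nadir, combined) and occlusion dropout of vegetation pixels,
preferentially low-canopy ones (mean rates 0.15 / 0.25 / 0.05). Both
vary from patch to patch (bias SD 0.12 / 0.15 / 0.04 m; dropout SD
0.08 / 0.10 / 0.02) — plant-level reconstruction instability from wind
and matching failures. This patch-level randomness is what makes
single-view features genuinely noisier rather than merely biased;
without it, a regression can compensate a constant bias perfectly and
all view sets would score alike. Magnitudes are plausible
structure-from-motion canopy-height error scales (roughly ±10–15 cm for
single views, ±4 cm combined).

**Color model.** Vegetation and soil reflectances are Gaussian around
green-shifted and brown means with SD 0.03, clipped to [0, 1]. Only the
rank structure of the vegetation indices matters downstream, so no
radiative-transfer realism is attempted.

**What passing tests do not show.** The simulator has no weather, soil,
or fertilizer process model; no orthomosaic stitching artifacts; no
inter-plant competition. Accuracy numbers obtained on synthetic feature
tables (e.g. R² near 0.95) exceed what field data yield; the tests
check *orderings and recoveries* (combined view ≥ single views;
parameters recovered; oracles matched), not absolute field performance.
Inter-plant variance structure is exposed as configuration rather than
claimed as fidelity.

## 2. Feature extraction

Seven variables per plant and view set, computed inside a 1 x 1 m
analysis polygon centered on the plant (pixel-center, half-open
membership):

* `A_proj` — vegetation-pixel count x pixel area (m²);
* `GRVI = (G-R)/(G+R)`, `GLI = (2G-R-B)/(2G+R+B)`,
  `VARI = (G-R)/(G+R-B)` — the standard forms of the cited indices;
* `GSI = (G - gray)/(G + gray)` with `gray = aR + (1-a)B`: a
  single-weight grayscale contrast. The exact published form of this
  index was not available to this implementation; the form here is
  consistent with a grayscale-conversion definition, has `a in [0,1]`,
  and is pluggable via configuration. The weight is optimized by grid
  argmax of the Pearson correlation between per-patch `GSI(a)` and
  `A_proj` (default grid 0–1 by 0.005, which represents the reference
  optimum 0.635 exactly; ties break toward smaller `a`);
* `H_max`, `H_ave` — DEM minus local ground, clipped at 0, max/mean over
  vegetation pixels. Ground is the 5th percentile of the in-polygon DEM
  (configurable); the percentile is robust to the few canopy pixels and
  to DEM noise, unlike the minimum.

Decisions where the protocol was under-specified: vegetation masking is
GLI thresholding with Otsu's automatic threshold (a reproducible
stand-in for interactive image thresholding; a fixed threshold is
available); indices are averaged over vegetation pixels only (a
whole-polygon mean is one flag away); per-pixel index denominators with
magnitude below 1e-9 exclude that pixel from that index's mean.

All three aggregates are verified against independent per-pixel
brute-force loops to 1e-9 on seeded simulated patches.

## 3. Biomass regression protocol

* 80/20 split (train size rounded half-up), seeded.
* Standardization to zero mean / unit variance is **fitted on the
  training subset only** and applied to the test subset. A literal
  "normalize everything, then split" reading leaks test moments into
  training; the package treats the anti-leakage order as the correct
  protocol. Zero-variance features are dropped with a logged warning.
  The response stays on its original scale, so RMSE is in g/plant.
* Exhaustive grid search with seeded 5-fold CV; selection by minimum
  mean CV RMSE for all algorithms (stated explicitly only for SVR in
  the reference protocol; adopted uniformly here). Grids: SVR
  `C in {1,5,10,50,100}`, `gamma in {0.01,0.05,0.1,0.5,1}`; RF 500
  unpruned trees, `mtry 1..4`, importance recorded as mean impurity
  decrease but not used for selection; XGB learning rate
  {0.01,0.1,0.3}, depth {3,6,9}, gamma {0,0.1,0.2}, subsample
  {0.6,0.8,1}, min child weight {1,3,5}, column subsample {0.6,0.8,1},
  with `nrounds` fixed at 100 (the reference protocol states no round
  count; 100 at these learning rates spans under- to well-fitted).
  Failed grid points are logged and excluded. Ties go to the earlier
  grid row. Single-threaded fits, so results are bit-reproducible.
* Stepwise regression: bidirectional selection by AIC
  (`n log(RSS/n) + 2(p+1)` convention via `stats::step`) from the
  intercept-only model. Note AIC's known liberality: each pure-noise
  candidate is admitted with probability ≈ 0.16, so the tested property
  is inclusion of the true support, not exact support identity.
* Evaluation: `R² = 1 - SS_res/SS_tot` about the test mean; subgroup
  reports reuse the single set of held-out predictions (no refitting),
  suppress groups under n = 3, and include the observed-on-predicted
  slope and intercept.
* SHAP: for the stepwise linear model, exact linear Shapley values
  (`beta_j (x_j - mean(bg_j))`, attributions only over selected
  features). For SVR/RF/XGB, a seeded permutation-sampling estimator
  telescoped against sampled background rows; the per-row baseline is
  the mean model value of the sampled background rows, which makes
  `baseline + sum(attributions) = prediction` exact up to floating
  point by construction. Default 64 permutations per explained row.

## 4. The growth model

Shoot biomass of genotype `g` at `t` DAP:

`f(t; theta_g) = A_g (1 + nu_g e^{-k_g (t - t_{i,g})})^{-1/nu_g} x e^{-d_g (t - t_{d,g})}`

with Gaussian observations `y ~ Normal(f, sigma_obs)` and a hierarchy
`theta_g ~ Normal(mu0, Sigma0)` on the transformed scale
`(log A, log nu, log k, t_i, log d, t_d)` (keeps positives positive; a
Normal law on the natural scale would put mass on invalid parameters).

**Decay conventions and identifiability.** Two readings of the decay
term are implemented. `as_printed` applies `e^{-d(t-t_d)}` at all
times — the factor *exceeds 1 before* `t_d`, and the triple
`(A, d, t_d)` then enters the curve only through `A e^{d t_d}` and `d`:
`A` and `t_d` are not separately identifiable from data, only their
product is. `gated` replaces the factor by 1 for `t < t_d`, treating
`t_d` as a true onset of senescence; every parameter is then
identifiable. `growth_curve` defaults to `as_printed` (the literal
equation); `fit_hierarchical`, `simulate_growth_series` and
`recovery_experiment` default to `gated`, without which the recovery
experiment is ill-posed (posterior means of `A` drift by factors of
2–3 along the `A`–`t_d` ridge). Evaluation is in log space
(`log1p(exp(.))` with the standard large-argument branches), stable for
large `|k (t - t_i)|`.

**Priors** (weakly informative, data-driven centers): `mu0` Normal with
centers log(max y) for `log A`, 0 for `log nu`, log(6/range(t)) for
`log k`, the time of the largest first difference of the pooled mean
trajectory for `t_i`, −4 for `log d`, and the *peak time of the pooled
mean trajectory* for `t_d` (an end-of-window center such as
`max(t) - 10` sits past the senescence window and destabilizes `t_d`);
SDs 1.5 on log scales and 40 d on time scales. Population SDs `sigma0`:
half-Normal with scales 1 (log scales) and 20 d (time scales);
`sigma_obs`: half-Normal scaled to `sd(y)`.

**Sampler.** The posterior is sampled with JAGS (adaptive Gibbs/slice
MCMC) under a *centered* hierarchy: each genotype contributes hundreds
of observations, so the centered form gives conjugate hyperparameter
updates and mixes better than the non-centered form here (the
non-centered trick pays off in data-poor regimes, not this one).
`Sigma0` is diagonal by default for sampling stability; a full
covariance mode (multivariate-normal hierarchy with a Wishart-type
precision prior) is available. Records are internally sorted, so fits
are invariant to input row order; per-chain RNG streams derive from one
seed; bad initializations retry up to 4 times with jittered starts.

**Iteration profiles and warm-up accounting.** `mcmc_config()` defaults
to 4 chains x 3,000 iterations with 500 warm-up, retaining
`4 x 2500 = 10,000` draws; warm-up covers sampler adaptation plus
burn-in (half each), both discarded. A scalar Gibbs/slice sampler
updates one coordinate at a time and therefore random-walks along the
correlated `(nu, k, t_i)` direction of slow-shaped genotypes (high
`nu`, low `k`), with much higher autocorrelation than a Hamiltonian
sampler at the same iteration count. Convergence-grade runs therefore
use `mcmc_config_long()` (4 x 12,000, 1,500 warm-up, a few minutes on
one CPU), which brings the maximum split-chain Gelman-Rubin statistic
of the full 12-genotype fit comfortably under 1.1. The reduced profile
`mcmc_config_reduced()` (4 x 1,000) is for smoke tests only and is not
expected to converge on the full problem.

**Diagnostics and summaries.** Split-chain Gelman-Rubin per parameter
(each chain halved, so within-chain drift registers); effective sample
sizes via `coda`; zero-variance draws flagged degenerate rather than
reported as converged. Summaries report medians, interquartile ranges
and central 99% intervals per parameter, and pointwise posterior mean
curves with central 95% bands by pushing (deterministically thinned)
draws through the curve.

**Recovery harness.** `recovery_experiment` simulates a series from
known parameters, refits, and reports per-parameter relative errors of
posterior means and 95%-interval coverage. At the reference design with
`sigma_obs` = 10% of mean `A`, the acceptance suite requires posterior
means of `A` within 15% of truth for at least 10 of 12 genotypes and
pooled coverage of at least 80%.

## 5. Time axis

Internally everything is days after transplanting (DAP). Calendar day
of year can be converted at I/O by subtracting the transplanting date;
the reference transplanting dates are late April / early May, so a
senescence onset of 190–200 DAP corresponds to the onset of the dry
season in early November.

## 6. Problem sizes used by the tests

Unit tests run the simulator at reduced sizes (tens of plants,
3-genotype series) and the full suite in well under half an hour on one
CPU. The acceptance checks use: the full field design for count checks;
50 seeded patches at 0.02 m pixels for the brute-force feature oracles;
10 seeded replicates of a 288-plant, 3-view field for the view-ordering
property; and one convergence-grade hierarchical fit of the full
3,168-record series shared by the convergence and recovery checks.
These sizes were chosen as the smallest at which the tested properties
are stable, and they are stated here so that a reader scaling the
package up knows which knobs were reduced (none, for the growth stage).

## 7. Known limitations

* The GSI definition is a documented reconstruction (see the feature-extraction section above), pluggable
  via configuration.
* The sampler is gradient-free; posterior geometry that NUTS traverses
  in thousands of iterations needs the longer profile here. Draws are
  exact MCMC either way — only efficiency differs.
* SHAP values for strongly correlated features (the four vegetation
  indices are nearly collinear by construction) attribute credit
  unstably between them; this is a property of marginal Shapley
  estimation, not of the models.
* The `as_printed` decay convention should be used for curve evaluation
  and display only; fitting under it estimates `A e^{d t_d}`, not `A`.
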