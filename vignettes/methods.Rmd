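---
title: "Methods: from censored soil chemistry to small-mammal density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from censored soil chemistry to small-mammal density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`scrsoil` implements an inference chain that asks whether the spatial
density of a small-mammal community responds to soil-chemical
concentrations: censored-data statistics and TEQ scoring for composite soil
samples, semivariogram-based ordinary kriging of concentration surfaces,
and full-likelihood spatial capture-recapture (SCR) with an inhomogeneous
Poisson density surface driven by the kriged chemistry. This vignette is
the package's account of the underlying models, the choices that were
genuinely open, and what the bundled synthetic data can and cannot show.

## Soil chemistry with nondetects

Laboratory reports censor concentrations below a reporting limit.
Records carry the substitution convention *nondetect = detection limit plus
a censored flag*; half-DL or zero substitution are deliberately not the
default (they distort rank statistics), though users can prepare inputs
either way. Group comparisons never pretend censored values are observed:

* `gehan_wilcoxon()` scores every cross-group pair +1/0/-1 by whether the
  ordering is unambiguous under left-censoring and computes a two-sided
  permutation p-value — complete enumeration of label assignments up to a
  pooled n of 10, Monte-Carlo beyond. Asymptotic p-values are deliberately
  avoided: with six composite samples per trapping grid the permutation
  distribution is the only trustworthy reference.
* `kruskal_dunn()` handles fully observed analytes: tie-corrected
  Kruskal-Wallis H (via `stats::kruskal.test`) followed, when the omnibus
  p < alpha, by Dunn's z on pooled mean ranks with Bonferroni adjustment.
* `screen_chemicals()` dispatches per analyte and retains those with
  among-grid p < 0.05. With three grids and any censoring, all grid pairs
  are compared by the Gehan test and Bonferroni-combined; the omnibus
  follow-up to a censored comparison is pairwise-Gehan-with-Bonferroni,
  chosen to mirror the Dunn-Bonferroni structure of the uncensored path.

TEQ scoring is the TEF-weighted sum over aryl-hydrocarbon-binding
congeners, with the WHO-2005 mammalian TEF table shipped as an editable CSV
(TCDD anchored at 1). TEQ records are treated as uncensored: they are sums
of detects and substituted nondetects, not laboratory measurements with
their own reporting limit, and the package exposes both test paths should
users prefer to treat heavily-censored TEQs with the Gehan test.

## Kriging

Chemicals that pass the screen are interpolated across the study strip.
The workflow this package mirrors used proprietary "empirical Bayesian kriging"; the
open surrogate here is ordinary kriging — best linear unbiased prediction
under an unknown constant mean, weights constrained to sum to one — with
the same three candidate semivariogram families (exponential, Whittle
(Matern nu = 1, via `besselK`), and power) and the same five leave-one-out
cross-validation criteria (ME, MSDE, MSE, RMSE, RMSSDE). Surfaces from the
surrogate will differ quantitatively from EBK output (EBK's subsetting and
semivariogram-simulation settings are proprietary and not reproducible), which is why the
chemical-coefficient checks downstream are soft.

Per analyte the workflow is: iterative Grubbs outlier screen at alpha =
0.01 (critical values from the t quantile formula); Shapiro-Wilk on the
outlier-free values with log transformation when p < 0.05 (concentrations
are positive; log-scale models are back-transformed with the lognormal
correction `exp(mu + sigma^2/2)`); WLS semivariogram fitting
(Cressie weights `n_pairs / gamma^2`) to a 10-bin empirical variogram up
to half the maximum pairwise lag — a standard default, as the reference
workflow does not state its binning; leave-one-out CV for each family; and
selection by the composite calibration score
`|MSDE| + |RMSSDE - 1| + |ME|/RMSE + |MSE - RMSE|/RMSE`, which encodes
"small bias, honest variance" as a single number. Outliers are excluded
from fitting but restored as conditioning data for the final surface, so
genuinely extreme measured concentrations still shape predictions near
their locations. Geostatistical anisotropy is intentionally out of scope:
directionality in this problem lives in the detection model.

## Spatial capture-recapture

The state space S is a habitat mask: lattice points at cell centers
(origin anchored at `(min_x - buffer, min_y - buffer)` of the trap
bounding box; the convention is fixed so point counts reproduce exactly),
keeping points within `buffer` of a trap. The default buffer is 200 m
(about 3 x the largest fitted sigma) and spacing 10 m (< 1 sigma, so mask
discretization bias is negligible); `fit_scr()` warns when spacing
exceeds the fitted sigma.

Detection is half-normal, `g(d) = g0 exp(-d^2 / 2 sigma^2)`, with
per-trap probabilities combined into multi-catch multinomial cells via
competing hazards `h_k = -log(1 - g_k)`:
`p_0 = exp(-H)`, `p_k = (h_k / H)(1 - exp(-H))`, `H = sum h_k`. Model
structure follows the conventional notation `D(~.) g0(~.) sigma(~.)`:

* **bk** — trap-specific learned response: the logit of g0 shifts by
  `beta_bk` only at traps that previously caught that individual.
* **mix** — latent two-class finite mixture on g0 and/or sigma with
  estimated proportion pi; sex or species grouping uses the same hybrid
  machinery with known memberships entering directly and unknowns
  marginalized over estimated class proportions. One class dimension per
  model.
* **anisotropy** — displacements are rotated into the canyon frame
  (`phi_a`, fixed at 1.8326 rad = 105 degrees from the landscape, never
  estimated) and the cross-axis component scaled by `phi_r`
  (log link, estimated), so detection range along the axis is `phi_r`
  times the perpendicular range. `phi_r` is not constrained above 1: the
  two regimes are the same family up to an axis swap, and the reference
  convention is ambiguous — a fitted `phi_r` of about 1.7 and about 1/1.7
  describe the same elongation under opposite conventions.

The full likelihood is the inhomogeneous-Poisson form with the spatial
integral replaced by the mask sum (cell area `a` in hectares):

```
logLik = -Lambda + sum_i log( sum_s D(s) a Pr(omega_i | s) ),
Lambda  = sum_s D(s) a p.(s),   D(s) = exp(beta0 + sum_j beta_j z_j(s))
```

with `Pr(omega_i | s)` the occasion-product of multinomial cells
marginalized over mixture classes and `p.(s)` the probability of at least
one capture. The additive `-log(n!)` constant is omitted; it cancels in
every AICc difference. Density covariates enter on their raw concentration
scale by default (coefficients are then per-ppm or per-ppt), with
standardization left to the user. AICc uses `n` = number of distinct
individuals, and models within 4 AICc units of the best are flagged
competing; `akaike_weights()` implements the usual exponential weights.

Numerical choices: all parameters are optimized on link scales (logit for
g0 and pi, log for sigma, density and phi_r); BFGS with `reltol = 1e-8`;
three optimizer starts by default — data-driven start values (g0 at the
naive capture frequency, sigma at half the mean recapture displacement,
mixture offsets nudged +1/-1 so the latent classes separate) plus jittered
restarts (sd 0.5 on the link scale), because the finite-mixture surface is
genuinely multimodal and single-start fits occasionally land on inverted-
anisotropy or collapsed-mixture modes. Standard errors come from the
inverse numerical Hessian; intervals are Wald on the link scale,
back-transformed (lognormal-style for density and abundance). Fits refuse
to run with fewer than two spatial recaptures (sigma unidentifiable),
flag non-convergence, and report absent standard errors rather than
inventing them when the Hessian is singular. Hazard matrices are cached by
the parameters they depend on, so finite-difference steps in density or
mixing parameters do not recompute mask-by-trap exponentials.

Single-catch traps are modeled with the multi-catch likelihood — the exact
single-catch likelihood remains unavailable — which is near-unbiased while
trap saturation stays low; the fitted data sit near 5% and `fit_scr()`
warns loudly past the 86% regime where the approximation breaks down.

## The pipeline

`run_pipeline()` chains the stages from one config: screen, krige retained
analytes onto the mask, fit the homogeneous-density detection set, retain
detection terms whose 95% CIs exclude zero (a deliberate CI rule, not
AICc, for the homogeneous-to-inhomogeneous handoff), carry anisotropy over
from the best homogeneous model, fit one log-linear density model per
kriged analyte with exactly those detection terms, and rank everything by
AICc. Density-chemical models are a priori hypothesis models: they are
flagged and reported even when their coefficients are uninformative.
The report's manifest (config + seed + versions) is sufficient to rerun
the pipeline bit-identically.

## The synthetic-data generator

`simulate_survey()` generates the study conditions the package targets:
three 5 x 20 trapping grids at 4.55 m spacing, grid centers about 170 m
apart along a 105-degree canyon axis, five occasions of single-catch
trapping; a community at 2.88 animals/ha with two latent detection classes
(29% with g0 = 0.04 and sigma = 71 m; 71% with g0 = 0.31 and sigma = 14
m), behavioral response +2.0 on logit(g0), and 1.7:1 home-range elongation
along the canyon. The cross-canyon grid stagger (0, 170, 55 m) is the one
free layout quantity; it was set once so the default layout reproduces the
reference 36-ha area of integration under the 200 m buffer. Chemical
fields are exact Cholesky draws of exponential-covariance Gaussian fields
on a coarse (20 m) raster — desk-scale rasters make exact simulation
cheap — with a canyon-axis trend supplying the among-grid differences the
screen should find, lognormal exponentiation for right-skewed analytes,
and detection limits that create realistic nondetect fractions. Composite
soil samples average five random points per subgrid (six subgrids per
grid) before lognormal measurement noise, mirroring the field protocol's
dilution of local extremes.

What the generator does *not* emulate: behavioral movement (activity
centers are fixed points, not home-range trajectories), temporal density
change within the survey, non-Poisson clustering of centers, and
chemical fields with nonstationary covariance. Passing tests therefore
demonstrate that the estimators recover the parameters of their own
generating model at the study's design and sample sizes — a necessary
check, not evidence about any particular real data set.

A practical consequence of those sample sizes: at the reference parameter
values the default design yields roughly 15-20 detected individuals per
realization, so single-realization estimates of the 8-parameter mixture
model are volatile (that is precisely why such designs yield wide
interval estimates). Validation checks therefore compare replicate
*medians* with reference intervals rather than asserting printed-precision
agreement from one realization.

## Problem sizes used in the test suite

Simulation-heavy checks run on a scaled-down survey — three 5 x 10 grids
at 4.55 m spacing, centers 100 m apart, 60 m buffer (3 sigma at the
simulated sigma = 20 m), 10 m mask — chosen so one simple-model fit takes
well under a second: 200 replicates for parameter recovery and coverage,
60 replicates for the single-catch-as-multi-catch bias check (at about 5%
trap saturation), and three full-design replicates for the stand-in
recovery of the reference estimates. Replicate counts are the package's
own design sizes, balancing Monte-Carlo error on a median (a few percent)
against suite runtime.

## Known limitations

* Ordinary kriging is a surrogate for proprietary EBK; surfaces and the
  soft chemical-coefficient checks inherit that difference.
* Wald/Hessian uncertainty for an 8-parameter mixture at n of about 20-30
  individuals is approximate; profile or bootstrap intervals would be the
  next step for real analyses.
* The likelihood's mask-sum integral is exact only in the fine-spacing
  limit; the 10 m default sits comfortably below sigma for the dominant
  detection class but users changing spacing should heed the warning.
* Sex/species grouping shares one class dimension with the latent mixture;
  crossing them (e.g. sex x mixture) is not supported.
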