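# scrsoil

Does the spatial density of a small-mammal community respond to the
soil chemicals beneath it? `scrsoil` implements the full inference chain
needed to ask that question directly, for ecotoxicologists and quantitative
ecologists monitoring contaminated or remediated sites with live-trapping
grids and composite soil sampling:

1. **Censored soil chemistry** — nondetects kept as left-censored values
   (substituted at the detection limit, flagged), compared among trapping
   grids with the Gehan-Wilcoxon permutation test or Kruskal-Wallis with
   Dunn-Bonferroni post hoc tests; dioxin/furan/PCB congeners collapsed to
   TEQ via WHO-2005 mammalian TEFs.
2. **Kriging** — per analyte: iterative Grubbs outlier screen, Shapiro-Wilk
   log-transform decision, semivariogram fitting (exponential, Whittle,
   power) by weighted least squares, ordinary-kriging surfaces with
   standard errors, and leave-one-out cross-validation (ME, MSDE, MSE,
   RMSE, RMSSDE) to pick the family.
3. **Spatial capture-recapture** — full-likelihood multi-catch SCR on a
   habitat mask `S`: half-normal detection
   `g(d) = g0 exp(-d^2 / 2 sigma^2)` with an anisotropic distance transform
   (fixed axis `phi_a`, estimated ratio `phi_r`), trap-learned behavioral
   response `bk`, latent two-class mixtures `pi` (or sex/species groups),
   and density as a homogeneous or log-linear inhomogeneous Poisson point
   process `D(s) = exp(beta0 + sum_j beta_j z_j(s))` over kriged chemical
   surfaces `z_j`. The log-likelihood is
   `-Lambda + sum_i log sum_s D(s) a Pr(omega_i | s)` with
   `Lambda = sum_s D(s) a p.(s)`. Models are ranked by AICc
   (`n` = individuals) with Akaike weights and a `delta <= 4` competing
   rule; abundance is derived as `N = sum_s D(s) a`.
4. **Synthetic data** — `simulate_survey()` generates the whole design
   (autocorrelated chemical fields, censored composites, a Poisson
   population, single- or multi-catch capture histories) so every stage is
   testable end to end without any external data.

## Worked example

Simulate a survey at the package's default study conditions (three 5 x 20
grids along a canyon, five occasions, two latent detection classes) and fit
the heterogeneity-plus-behavior model with anisotropic detection:

```r
library(scrsoil)

sim <- simulate_survey(sim_config(analytes = list()), seed = 11)
capture_summary(sim$captures)
#> # A tibble: 1 x 7
#>   n_individuals n_captures n_recaptures n_spatial_recaptures mean_recaptures ...
#> 1            16         44           28                   26            1.75

spec <- scr_model_spec(D = ~1, g0 = ~bk + mix, sigma = ~mix,
                       anisotropy = TRUE, phi_a = 1.8326)
fit <- fit_scr(sim$captures, sim$traps, sim$mask, spec)
real_params(fit)
#> # A tibble: 8 x 5
#>   parameter class    estimate     lcl     ucl
#> 1 D         ""         1.21    0.246   5.96
#> 2 g0        "class1"   0.0274  0.0103  0.0710
#> 3 g0        "class2"   0.125   0.0129  0.609
#> 4 sigma     "class1"  40.3    22.5    72.0
#> 5 sigma     "class2"  12.8     4.11   40.1
#> 6 beta_bk   ""         2.11    0.826   3.40
#> 7 pi        "class2"   0.409   0.0145  0.970
#> 8 phi_r     ""         0.535   0.105   2.72
derived_abundance(fit)
#> # A tibble: 1 x 4
#>   N_hat   lcl   ucl area_ha
#> 1  43.8  8.91  209.    36.2
```

Read: the two latent classes split into a wide-ranging, trap-shy class
(`sigma` about 40 m, `g0` about 0.03) and a short-range, trappable class;
capture probability rises sharply after an individual's first capture in a
trap (`beta_bk` about 2 on the logit scale); and the density intercept
converts to an abundance estimate over the 36-ha state space. A single
16-individual realization carries wide intervals — the generating values
(D = 2.88/ha, beta_bk = 2.0, phi_r = 1.7) sit inside every one of them.
`tidy(fit)`, `glance(fit)`, `autoplot(fit)` and `plot_density_surface(fit)`
give link-scale coefficients, one-line summaries, detection-function and
density-surface plots; `model_table(list_of_fits)` builds the AICc table.

The full soil-to-density pipeline (screen, krige, detection stage,
inhomogeneous density stage, AICc ranking) runs from one config:

```r
report <- run_pipeline(list(simulate = sim_config(), n_starts = 1), seed = 1)
report$model_table
```

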