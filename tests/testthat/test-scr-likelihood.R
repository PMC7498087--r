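toy_problem <- function() {
  traps <- trap_array(tibble::tibble(trap_id = c("A", "B", "C"),
                                     x = c(-6, 0, 6), y = c(0, 3, 0)))
  mask <- build_mask(traps, buffer = 25, spacing = 11) # small point set
  cd <- capture_data(
    tibble::tibble(individual_id = c("i1", "i1", "i2"),
                   occasion = c(1L, 2L, 2L),
                   trap_id = c("A", "B", "B")),
    traps, n_occasions = 2
  )
  list(traps = traps, mask = mask, captures = cd)
}

test_that("history probabilities sum to one over all possible histories", {
  tp <- toy_problem()
  trap_xy <- as.matrix(tp$traps[, c("x", "y")])
  hists <- as.matrix(tidyr::expand_grid(h1 = 0:3, h2 = 0:3))
  for (s in list(c(0, 0), c(10, -4), c(-20, 15))) {
    tot <- sum(apply(hists, 1, function(h) {
      oracle_history_prob(s[1], s[2], trap_xy, h, g0 = 0.3, sigma = 8,
                          beta_bk = 1.2)
    }))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("the likelihood matches the brute-force oracle on the toy problem", {
  tp <- toy_problem()
  set.seed(17)
  for (rep in 1:5) {
    D <- runif(1, 0.5, 4)
    g0 <- runif(1, 0.1, 0.5)
    sigma <- runif(1, 5, 15)
    bbk <- rnorm(1, 0, 1)
    spec <- scr_model_spec(D = ~1, g0 = ~bk, sigma = ~1)
    par <- scr_par_template(spec, tp$captures)
    par[c("D.(Intercept)", "g0.(Intercept)", "g0.bk",
          "sigma.(Intercept)")] <- c(log(D), qlogis(g0), bbk, log(sigma))
    ll <- scr_loglik(par, tp$captures, tp$traps, tp$mask, spec)
    ll_or <- oracle_loglik(D, g0, sigma, bbk, tp$captures, tp$traps,
                           tp$mask)
    expect_equal(ll, ll_or, tolerance = 1e-10)
  }
})

test_that("the anisotropic likelihood matches the oracle", {
  tp <- toy_problem()
  spec <- scr_model_spec(D = ~1, g0 = ~1, sigma = ~1, anisotropy = TRUE,
                         phi_a = 0.9)
  par <- scr_par_template(spec, tp$captures)
  par[] <- c(log(2), qlogis(0.25), log(9), log(1.6))
  ll <- scr_loglik(par, tp$captures, tp$traps, tp$mask, spec)
  ll_or <- oracle_loglik(2, 0.25, 9, 0, tp$captures, tp$traps, tp$mask,
                         phi_a = 0.9, phi_r = 1.6)
  expect_equal(ll, ll_or, tolerance = 1e-10)
})

test_that("mixture likelihood reduces to a psi-weighted oracle mixture", {
  tp <- toy_problem()
  spec <- scr_model_spec(D = ~1, g0 = ~mix, sigma = ~mix)
  par <- scr_par_template(spec, tp$captures)
  g0_1 <- 0.12; g0_2 <- 0.45; s1 <- 12; s2 <- 6; pi2 <- 0.64; D <- 1.7
  par[c("D.(Intercept)", "g0.(Intercept)", "g0.mixclass2",
        "sigma.(Intercept)", "sigma.mixclass2", "psi.class2")] <-
    c(log(D), qlogis(g0_1), qlogis(g0_2) - qlogis(g0_1),
      log(s1), log(s2 / s1), qlogis(pi2))
  ll <- scr_loglik(par, tp$captures, tp$traps, tp$mask, spec)

  # oracle: marginalize classes by hand
  trap_xy <- as.matrix(tp$traps[, c("x", "y")])
  a <- mask_spacing(tp$mask)^2 / 1e4
  hists <- list(i1 = c(1L, 2L), i2 = c(0L, 2L))
  mix_pr <- function(s, h) {
    (1 - pi2) * oracle_history_prob(s[1], s[2], trap_xy, h, g0_1, s1) +
      pi2 * oracle_history_prob(s[1], s[2], trap_xy, h, g0_2, s2)
  }
  S <- as.matrix(tp$mask[, c("x", "y")])
  pdot <- apply(S, 1, function(s) 1 - mix_pr(s, c(0L, 0L)))
  ll_or <- -sum(D * a * pdot)
  for (h in hists) {
    ll_or <- ll_or + log(sum(D * a * apply(S, 1, mix_pr, h = h)))
  }
  expect_equal(ll, ll_or, tolerance = 1e-10)
})

test_that("nested models reproduce reduced log-likelihoods exactly", {
  tp <- toy_problem()
  base <- scr_model_spec(D = ~1, g0 = ~1, sigma = ~1)
  par0 <- scr_par_template(base, tp$captures)
  par0[] <- c(log(1.5), qlogis(0.3), log(8))
  ll0 <- scr_loglik(par0, tp$captures, tp$traps, tp$mask, base)

  # bk coefficient at zero
  spb <- scr_model_spec(D = ~1, g0 = ~bk, sigma = ~1)
  pb <- scr_par_template(spb, tp$captures)
  pb[c("D.(Intercept)", "g0.(Intercept)", "g0.bk", "sigma.(Intercept)")] <-
    c(par0[1:2], 0, par0[3])
  expect_equal(scr_loglik(pb, tp$captures, tp$traps, tp$mask, spb), ll0,
               tolerance = 1e-8)

  # phi_r at one
  spa <- scr_model_spec(D = ~1, g0 = ~1, sigma = ~1, anisotropy = TRUE,
                        phi_a = 1.1)
  pa <- scr_par_template(spa, tp$captures)
  pa[] <- c(par0, 0)
  expect_equal(scr_loglik(pa, tp$captures, tp$traps, tp$mask, spa), ll0,
               tolerance = 1e-8)

  # mixture offsets at zero (any psi)
  spm <- scr_model_spec(D = ~1, g0 = ~mix, sigma = ~mix)
  pm <- scr_par_template(spm, tp$captures)
  pm[c("D.(Intercept)", "g0.(Intercept)", "sigma.(Intercept)")] <- par0
  pm["psi.class2"] <- 0.83
  expect_equal(scr_loglik(pm, tp$captures, tp$traps, tp$mask, spm), ll0,
               tolerance = 1e-8)

  # density coefficient at zero on a mask covariate
  mask2 <- tp$mask
  mask2$chem <- runif(nrow(mask2))
  spd <- scr_model_spec(D = ~chem, g0 = ~1, sigma = ~1)
  pd <- scr_par_template(spd, tp$captures)
  pd[c("D.(Intercept)", "D.chem", "g0.(Intercept)",
       "sigma.(Intercept)")] <- c(par0[1], 0, par0[2:3])
  expect_equal(scr_loglik(pd, tp$captures, tp$traps, mask2, spd), ll0,
               tolerance = 1e-8)
})

test_that("simulated history frequencies match modeled probabilities", {
  # one animal at a fixed center, two traps, one occasion: the multinomial
  # cells of the observation model against 1e5 simulated draws
  traps <- trap_array(tibble::tibble(trap_id = c("A", "B"),
                                     x = c(-5, 5), y = 0))
  pop <- tibble::tibble(x = 2, y = 1, sex = "M", species = "sp",
                        class = 1L)
  d <- sqrt((traps$x - 2)^2 + (0 - 1)^2)
  cells <- multicatch_probs(halfnormal_g(d, 0.4, 6))$prob
  n_draw <- 1e5 # occasions are iid draws with no behavioral response
  sim <- simulate_captures(pop, traps, n_occasions = n_draw, g0 = 0.4,
                           sigma = 6, beta_bk = 0, mode = "multi",
                           seed = 99)
  counts <- c(n_draw - nrow(sim),
              sum(sim$trap_id == "A"), sum(sim$trap_id == "B"))
  gof <- suppressWarnings(chisq.test(counts, p = cells))
  expect_gt(gof$p.value, 0.001)
})

test_that("missing density covariates are reported", {
  tp <- toy_problem()
  spd <- scr_model_spec(D = ~nope, g0 = ~1, sigma = ~1)
  par <- scr_par_template(spd, tp$captures)
  expect_error(scr_loglik(par, tp$captures, tp$traps, tp$mask, spd),
               "lacks density covariate")
})
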