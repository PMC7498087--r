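test_that("a simple fit recovers its generating parameters on one data set", {
  geo <- small_geometry()
  set.seed(20)
  pop <- simulate_population(geo$mask, density = 3, pi_class = c(1, 0))
  cd <- simulate_captures(pop, geo$traps, n_occasions = 5, g0 = 0.2,
                          sigma = 20, phi_r = 1, mode = "multi")
  fit <- fit_scr(cd, geo$traps, geo$mask, scr_model_spec(), n_starts = 1)
  expect_true(fit$converged)
  rp <- real_params(fit)
  D_row <- rp[rp$parameter == "D", ]
  expect_true(D_row$lcl < 3 && 3 < D_row$ucl)
  sig_row <- rp[rp$parameter == "sigma", ]
  expect_gt(sig_row$estimate, 10)
  expect_lt(sig_row$estimate, 40)
  ab <- derived_abundance(fit)
  expect_equal(ab$N_hat, D_row$estimate * mask_area(geo$mask),
               tolerance = 1e-8)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_density_surface(fit), "ggplot")
  td <- tidy(fit)
  expect_identical(nrow(td), fit$K)
  gl <- glance(fit)
  expect_equal(gl$AICc, aicc(fit$loglik, fit$K, fit$n))
})

test_that("fits without identifiable information are refused", {
  tr <- toy_traps(4)
  mask <- build_mask(tr, 50, 10)
  no_recap <- capture_data(
    tibble::tibble(individual_id = c("a", "b"), occasion = 1:2,
                   trap_id = c("t1", "t3")),
    tr, n_occasions = 5
  )
  expect_error(fit_scr(no_recap, tr, mask, scr_model_spec()),
               "no recaptures")
  one_spatial <- capture_data(
    tibble::tibble(individual_id = c("a", "a", "b", "b"),
                   occasion = c(1, 2, 1, 2),
                   trap_id = c("t1", "t2", "t3", "t3")),
    tr, n_occasions = 5
  )
  expect_error(fit_scr(one_spatial, tr, mask, scr_model_spec()),
               "spatial recaptures")
})

test_that("misnamed start vectors are rejected", {
  geo <- small_geometry()
  set.seed(4)
  pop <- simulate_population(geo$mask, density = 3, pi_class = c(1, 0))
  cd <- simulate_captures(pop, geo$traps, n_occasions = 5, g0 = 0.3,
                          sigma = 20, phi_r = 1, mode = "multi")
  bad <- c(a = 1, b = 2, c = 3)
  expect_error(fit_scr(cd, geo$traps, geo$mask, scr_model_spec(),
                       start = bad), "must carry names")
})

test_that("density estimates are insensitive to buffer growth beyond 3 sigma", {
  # with sigma = 20 m, widening the buffer from 3 to 4 sigma must leave
  # D essentially unchanged (all centers with non-negligible capture
  # probability are already inside)
  traps <- sim_trap_grids(n_grids = 2, n_rows = 5, n_cols = 10,
                          trap_spacing = 4.55, center_spacing = 80,
                          lateral_offsets = c(0, 30), axis = 0)
  set.seed(33)
  mask4 <- build_mask(traps, buffer = 80, spacing = 10)
  pop <- simulate_population(mask4, density = 3, pi_class = c(1, 0))
  cd <- simulate_captures(pop, traps, n_occasions = 5, g0 = 0.25,
                          sigma = 20, phi_r = 1, mode = "multi")
  mask3 <- build_mask(traps, buffer = 60, spacing = 10)
  f3 <- fit_scr(cd, traps, mask3, scr_model_spec(), n_starts = 1)
  f4 <- fit_scr(cd, traps, mask4, scr_model_spec(), n_starts = 1)
  D3 <- real_params(f3)$estimate[1]
  D4 <- real_params(f4)$estimate[1]
  expect_lt(abs(D4 - D3) / D3, 0.01)
})
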