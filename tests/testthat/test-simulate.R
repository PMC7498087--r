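test_that("the same seed reproduces every simulated output exactly", {
  cfg <- sim_config(n_cols = 6, buffer = 60, mask_spacing = 10,
                    analytes = list(
                      Hg = list(mean = -3, sill = 0.4, range = 80,
                                trend = -0.004, lognormal = TRUE,
                                detection_limit = 0.03)
                    ))
  s1 <- simulate_survey(cfg, seed = 5)
  s2 <- simulate_survey(cfg, seed = 5)
  expect_identical(s1$traps, s2$traps)
  expect_identical(s1$population, s2$population)
  expect_identical(tibble::as_tibble(s1$captures),
                   tibble::as_tibble(s2$captures))
  expect_identical(s1$samples, s2$samples)
  s3 <- simulate_survey(cfg, seed = 6)
  expect_false(identical(s1$population, s3$population))
})

test_that("field simulation honors degenerate settings", {
  pts <- tidyr::expand_grid(x = seq(0, 90, 10), y = seq(0, 90, 30))
  flat <- simulate_field(pts, mean = 7, sill = 0, trend = 0)
  expect_true(all(flat$value == 7))
  ln <- simulate_field(pts, mean = 0, sill = 0.5, range = 50,
                       lognormal = TRUE, seed = 2)
  expect_true(all(ln$value > 0))
})

test_that("composite sampling censors at the detection limit", {
  traps <- sim_trap_grids(n_grids = 2, n_rows = 3, n_cols = 6,
                          trap_spacing = 5, center_spacing = 60,
                          lateral_offsets = c(0, 10), axis = 0)
  pts <- scrsoil:::field_raster(traps, 40, 15)
  fld <- simulate_field(pts, mean = 1, sill = 0.1, range = 50, seed = 3)
  samp <- simulate_soil_samples(fld, traps, analyte = "x",
                                detection_limit = 1e6, seed = 4)
  expect_true(all(samp$censored)) # DL above every value
  expect_true(all(samp$concentration == samp$detection_limit))
  expect_identical(nrow(samp), 12L) # 2 grids x 6 subgrids
  samp2 <- simulate_soil_samples(fld, traps, analyte = "x",
                                 detection_limit = 0, seed = 4)
  expect_false(any(samp2$censored))
})

test_that("population counts follow the intensity and covariate direction", {
  traps <- toy_traps(5, spacing = 20)
  mask <- build_mask(traps, buffer = 50, spacing = 10)
  set.seed(44)
  counts <- replicate(200, nrow(simulate_population(mask, density = 2.88)))
  expected <- 2.88 * mask_area(mask)
  expect_equal(mean(counts), expected, tolerance = 0.05)
  expect_equal(var(counts), expected, tolerance = 0.25) # Poisson dispersion

  # strongly negative coefficient empties the high-covariate cells
  mask$chem <- as.numeric(mask$x > mean(mask$x))
  set.seed(45)
  pops <- purrr::map_dfr(1:50, function(i) {
    simulate_population(mask, density = 3, d_covs = "chem", d_betas = -8)
  })
  frac_high <- mean(pops$x > mean(mask$x))
  expect_lt(frac_high, 0.05)
  expect_error(simulate_population(mask, density = 1e7), "exceeds 1e6")
})

test_that("capture simulation matches closed-form capture counts", {
  traps <- trap_array(tibble::tibble(trap_id = "t1", x = 0, y = 0))
  pop <- tibble::tibble(x = 0, y = 0, sex = "F", species = "sp",
                        class = 1L)
  # one animal on the trap, g0 = 0.3, 5 occasions: E[captures] = 5 * 0.3
  set.seed(31)
  caps <- replicate(400, {
    nrow(simulate_captures(pop, traps, n_occasions = 5, g0 = 0.3,
                           sigma = 10, mode = "multi"))
  })
  expect_equal(mean(caps), 1.5, tolerance = 0.05)

  # g0 = 0 yields no captures at all
  none <- simulate_captures(pop, traps, n_occasions = 5, g0 = 0,
                            sigma = 10, mode = "multi")
  expect_identical(nrow(none), 0L)
})

test_that("single-catch dynamics never double-book animals or traps", {
  geo <- small_geometry()
  set.seed(52)
  pop <- simulate_population(geo$mask, density = 6, pi_class = c(1, 0))
  cd <- simulate_captures(pop, geo$traps, n_occasions = 5, g0 = 0.4,
                          sigma = 20, mode = "single")
  per_occ <- tibble::as_tibble(cd) |>
    dplyr::group_by(occasion) |>
    dplyr::summarise(
      dup_trap = anyDuplicated(trap_id) > 0,
      dup_animal = anyDuplicated(individual_id) > 0
    )
  expect_false(any(per_occ$dup_trap))
  expect_false(any(per_occ$dup_animal))
})
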