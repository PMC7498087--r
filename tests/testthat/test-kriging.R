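make_samples <- function(n = 8, seed = 4, range = 40) {
  set.seed(seed)
  pts <- tibble::tibble(x = runif(n, 0, 100), y = runif(n, 0, 100))
  simulate_field(pts, mean = 10, sill = 2, range = range)
}

test_that("ordinary kriging interpolates exactly at nugget zero", {
  s <- make_samples()
  m <- variogram_model("exponential", nugget = 0, psill = 2, range = 40)
  k <- krige(m, s, s[, c("x", "y")])
  expect_equal(k$prediction, s$value, tolerance = 1e-8)
  expect_equal(k$standard_error, rep(0, nrow(s)), tolerance = 1e-6)
})

test_that("kriging weights sum to one at arbitrary targets", {
  s <- make_samples(10)
  m <- variogram_model("whittle", nugget = 0.1, psill = 2, range = 30)
  set.seed(6)
  for (i in 1:10) {
    w <- kriging_weights(m, s, runif(2, -20, 120))
    expect_equal(sum(w), 1, tolerance = 1e-10)
  }
})

test_that("predictions are shift-equivariant", {
  s <- make_samples(9)
  m <- variogram_model("exponential", nugget = 0.2, psill = 1.5, range = 25)
  targets <- tibble::tibble(x = c(10, 55, 90), y = c(80, 20, 50))
  k1 <- krige(m, s, targets)
  s2 <- dplyr::mutate(s, value = value + 100)
  k2 <- krige(m, s2, targets)
  expect_equal(k2$prediction, k1$prediction + 100, tolerance = 1e-8)
  expect_equal(k2$standard_error, k1$standard_error, tolerance = 1e-10)
})

test_that("a single sample predicts its own value everywhere", {
  s <- tibble::tibble(x = 5, y = 5, value = 7.3)
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 10)
  k <- krige(m, s, tibble::tibble(x = c(0, 50, 500), y = 0))
  expect_equal(k$prediction, rep(7.3, 3))
})

test_that("duplicate sample locations are rejected with their coordinates", {
  s <- tibble::tibble(x = c(1, 2, 1), y = c(1, 2, 1), value = 1:3)
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 10)
  expect_error(krige(m, s, tibble::tibble(x = 0, y = 0)), "\\(1, 1\\)")
})

test_that("log-scale models back-transform with the lognormal correction", {
  s <- make_samples(8)
  s$value <- exp(s$value / 5) # positive, skewed
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 40,
                       log_transformed = TRUE)
  k <- krige(m, s, s[1:3, c("x", "y")])
  # at sample points kriging variance is 0, so back-transform is exact
  expect_equal(k$prediction, s$value[1:3], tolerance = 1e-7)
  expect_true(all(k$prediction > 0))
})

test_that("denser sampling of a smooth field reduces prediction error", {
  set.seed(77)
  truth <- function(p) simulate_field(p, mean = 0, sill = 1, range = 60)
  grid <- tidyr::expand_grid(x = seq(5, 95, 10), y = seq(5, 95, 10))
  all_pts <- dplyr::bind_rows(
    grid,
    tibble::tibble(x = runif(160, 0, 100), y = runif(160, 0, 100))
  )
  fld <- truth(all_pts)
  target_idx <- seq_len(nrow(grid))
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 60)
  rmse_at <- function(n_samp) {
    idx <- nrow(grid) + seq_len(n_samp)
    k <- krige(m, fld[idx, ], fld[target_idx, c("x", "y")])
    sqrt(mean((k$prediction - fld$value[target_idx])^2))
  }
  expect_lt(rmse_at(160), rmse_at(25))
})

test_that("cross-validation metrics satisfy their identities and directions", {
  s <- make_samples(25, seed = 13)
  m_true <- fit_variogram(s, "exponential")
  cv <- cross_validate(m_true, s)
  expect_gte(cv$RMSE, abs(cv$ME))
  expect_gte(cv$RMSSDE, abs(cv$MSDE))
  expect_gte(cv$MSE, 0)
  # overstating the sill deflates standardized errors
  m_infl <- variogram_model("exponential", nugget = m_true$nugget,
                            psill = m_true$psill * 10,
                            range = m_true$range)
  cv_infl <- cross_validate(m_infl, s)
  expect_lt(cv_infl$RMSSDE, cv$RMSSDE)
  expect_lt(cv_infl$RMSSDE, 0.6)
})

test_that("selection workflow flags outliers, picks a family, and restores outliers", {
  set.seed(21)
  s <- make_samples(17, seed = 21, range = 30)
  s$value[5] <- s$value[5] + 40 # gross outlier
  sel <- select_variogram(s)
  expect_true(5 %in% sel$outliers)
  expect_identical(sum(sel$cv$selected), 1L)
  expect_true(all(c("ME", "MSDE", "MSE", "RMSE", "RMSSDE") %in%
                    names(sel$cv)))
  surf <- predict_surface(sel, tibble::tibble(x = s$x[5], y = s$y[5]))
  # outlier kept as conditioning data: prediction honors it at nugget ~ 0
  if (sel$model$nugget < 1e-6 && !sel$model$log_transformed) {
    expect_equal(surf$prediction, s$value[5], tolerance = 1e-6)
  }
  expect_s3_class(autoplot(sel$model), "ggplot")
  full <- predict_surface(sel, tidyr::expand_grid(x = seq(0, 100, 20),
                                                  y = seq(0, 100, 20)))
  expect_s3_class(autoplot(full), "ggplot")
  expect_s3_class(autoplot(full, "standard_error"), "ggplot")
  expect_true(all(full$standard_error >= 0))
})
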