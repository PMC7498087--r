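#' Ordinary kriging prediction
#'
#' Solves the ordinary-kriging system (semivariogram form, with the Lagrange
#' multiplier enforcing that weights sum to one) at each target point.
#' Ordinary kriging is the best linear unbiased predictor under an unknown
#' constant mean -- the open surrogate used here for proprietary empirical
#' Bayesian kriging, keeping the same candidate semivariogram families and
#' cross-validation criteria.
#'
#' For models fitted on the log scale, predictions are back-transformed with
#' the lognormal correction `exp(mu + sigma^2/2)` where `sigma^2` is the
#' kriging variance, and the reported standard error is the lognormal
#' standard deviation `prediction * sqrt(exp(sigma^2) - 1)`.
#'
#' @param model A fitted [variogram_model()].
#' @param samples Data frame with `x`, `y` and a value column
#'   (`concentration` or `value`); sample locations must be distinct.
#' @param targets Data frame of target points with `x`, `y` (e.g. a
#'   [build_mask()] mask or raster cell centers).
#' @return Tibble of class `kriging_surface`: `x`, `y`, `prediction`,
#'   `standard_error`.
#' @export
krige <- function(model, samples, targets) {
  xy <- as.matrix(samples[, c("x", "y")])
  dup <- duplicated(round(xy, 9))
  if (any(dup)) {
    abort(paste0(
      "duplicate sample locations make the kriging system singular: (",
      paste(apply(unique(xy[dup, , drop = FALSE]), 1, paste, collapse = ", "),
            collapse = "), ("), ")"
    ))
  }
  if (any(!is.finite(as.matrix(targets[, c("x", "y")])))) {
    abort("target coordinates must be finite")
  }
  z <- sample_values(samples, isTRUE(model$log_transformed))
  n <- nrow(xy)

  gamma_ss <- semivariance(model, as.matrix(dist(xy)))
  a_mat <- rbind(cbind(gamma_ss, 1), c(rep(1, n), 0))
  a_lu <- tryCatch(solve(a_mat), error = function(e) {
    abort("singular kriging system; check sample geometry")
  })

  tx <- targets$x; ty <- targets$y
  m <- length(tx)
  pred <- numeric(m); kvar <- numeric(m)
  block <- 2000L
  for (i0 in seq(1L, m, by = block)) {
    idx <- i0:min(i0 + block - 1L, m)
    d0 <- sqrt(outer(tx[idx], xy[, 1], "-")^2 +
                 outer(ty[idx], xy[, 2], "-")^2)
    g0 <- matrix(semivariance(model, d0), nrow = length(idx))
    b <- rbind(t(g0), 1)                    # (n+1) x m block
    lam <- a_lu %*% b
    pred[idx] <- drop(crossprod(lam[seq_len(n), , drop = FALSE], z))
    kvar[idx] <- colSums(lam * b)           # sum(lambda * gamma0) + mu
  }
  kvar <- pmax(kvar, 0)
  if (isTRUE(model$log_transformed)) {
    mu <- pred
    pred <- exp(mu + kvar / 2)
    se <- pred * sqrt(pmax(exp(kvar) - 1, 0))
  } else {
    se <- sqrt(kvar)
  }
  out <- tibble::tibble(x = tx, y = ty, prediction = pred,
                        standard_error = se)
  class(out) <- c("kriging_surface", class(tibble::tibble()))
  out
}

#' Kriging weights at a single target
#'
#' Exposes the ordinary-kriging weight vector (used by the unbiasedness
#' checks: weights must sum to one at every target).
#'
#' @inheritParams krige
#' @param target Length-2 numeric `c(x, y)`.
#' @return Numeric weights, one per sample.
#' @export
kriging_weights <- function(model, samples, target) {
  xy <- as.matrix(samples[, c("x", "y")])
  n <- nrow(xy)
  gamma_ss <- semivariance(model, as.matrix(dist(xy)))
  a_mat <- rbind(cbind(gamma_ss, 1), c(rep(1, n), 0))
  d0 <- sqrt((xy[, 1] - target[1])^2 + (xy[, 2] - target[2])^2)
  sol <- solve(a_mat, c(semivariance(model, d0), 1))
  sol[seq_len(n)]
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Each sample is predicted from the others; with prediction errors
#' `e_i = prediction_i - observed_i` and kriging standard errors `s_i`
#' (both on the observation scale):
#' `ME = mean(e)`, `MSDE = mean(e/s)`, `MSE = mean(s)`,
#' `RMSE = sqrt(mean(e^2))`, `RMSSDE = sqrt(mean((e/s)^2))`.
#' A well-calibrated model has small `|ME|` and `|MSDE|`, `RMSSDE` near 1,
#' and `MSE` close to `RMSE`; `RMSSDE` below 1 means the model overstates
#' its own uncertainty, above 1 understates it.
#'
#' @param model A fitted [variogram_model()].
#' @param samples Data frame with `x`, `y` and a value column; at least 5.
#' @return One-row tibble of class `cv_metrics` with columns `ME`, `MSDE`,
#'   `MSE`, `RMSE`, `RMSSDE`, `n_used`.
#' @export
cross_validate <- function(model, samples) {
  if (nrow(samples) < 5L) abort("need at least five samples for cross-validation")
  n <- nrow(samples)
  vcol <- intersect(c("concentration", "value"), names(samples))[1]
  obs <- as.numeric(samples[[vcol]])
  e <- numeric(n); s <- numeric(n)
  for (i in seq_len(n)) {
    ki <- krige(model, samples[-i, ], samples[i, c("x", "y")])
    e[i] <- ki$prediction - obs[i]
    s[i] <- ki$standard_error
  }
  usable <- s > 0
  if (!all(usable)) {
    warn(paste0(sum(!usable),
                " point(s) with zero kriging SE skipped in standardized metrics"))
  }
  out <- tibble::tibble(
    ME = mean(e),
    MSDE = mean(e[usable] / s[usable]),
    MSE = mean(s),
    RMSE = sqrt(mean(e^2)),
    RMSSDE = sqrt(mean((e[usable] / s[usable])^2)),
    n_used = sum(usable)
  )
  class(out) <- c("cv_metrics", class(tibble::tibble()))
  out
}

#' Fit, cross-validate and select a semivariogram for one chemical
#'
#' The full per-analyte kriging workflow: (1) screen for outliers with
#' [grubbs_iterative()]; (2) test normality of the outlier-free values with
#' [shapiro_wilk()] and log-transform when `p < 0.05` (concentrations cannot
#' be negative); (3) fit every candidate family to the outlier-free samples;
#' (4) leave-one-out cross-validate each; (5) pick the family minimizing a
#' composite calibration score
#' `|MSDE| + |RMSSDE - 1| + |ME|/RMSE + |MSE - RMSE|/RMSE`
#' (small bias, standardized errors near unit variance, agreement between
#' claimed and realized error). Outliers are excluded from fitting but kept
#' as conditioning data for final prediction via [predict_surface()].
#'
#' @param samples Data frame with `x`, `y` and a value column.
#' @param families Candidate families.
#' @param log_transform `"auto"` (Shapiro-Wilk decision), `TRUE` or `FALSE`.
#' @param alpha_outlier Grubbs level.
#' @param n_bins,max_lag Passed to [fit_variogram()].
#' @return List of class `variogram_selection`: `model` (the winner), `fits`
#'   (all families), `cv` (one row per family with a `selected` flag),
#'   `outliers` (indices), `shapiro`, `log_transformed`, `samples`.
#' @export
select_variogram <- function(samples,
                             families = c("exponential", "whittle", "power"),
                             log_transform = "auto", alpha_outlier = 0.01,
                             n_bins = 10, max_lag = NULL) {
  vcol <- intersect(c("concentration", "value"), names(samples))[1]
  if (is.na(vcol)) abort("samples need a 'concentration' or 'value' column")
  vals <- as.numeric(samples[[vcol]])
  out_idx <- grubbs_iterative(vals, alpha = alpha_outlier)
  clean <- if (length(out_idx)) samples[-out_idx, ] else samples
  sw <- shapiro_wilk(as.numeric(clean[[vcol]]))
  logt <- if (identical(log_transform, "auto")) sw$p_value < 0.05 else
    isTRUE(log_transform)

  fits <- purrr::map(setNames(families, families), function(fam) {
    fit_variogram(clean, family = fam, log_transform = logt,
                  n_bins = n_bins, max_lag = max_lag)
  })
  cv <- purrr::map_dfr(fits, function(m) cross_validate(m, clean),
                       .id = "family")
  score <- with(cv, abs(MSDE) + abs(RMSSDE - 1) + abs(ME) / RMSE +
                  abs(MSE - RMSE) / RMSE)
  cv$score <- score
  cv$selected <- seq_len(nrow(cv)) == which.min(score)
  structure(
    list(model = fits[[which.min(score)]], fits = fits, cv = cv,
         outliers = out_idx, shapiro = sw, log_transformed = logt,
         samples = samples),
    class = "variogram_selection"
  )
}

#' @export
print.variogram_selection <- function(x, ...) {
  cat("Semivariogram selection over", nrow(x$cv), "families\n")
  cat("  outliers flagged:", length(x$outliers),
      " log scale:", x$log_transformed,
      sprintf(" (Shapiro-Wilk W = %.2f, p = %.3g)\n",
              x$shapiro$W, x$shapiro$p_value))
  print(dplyr::select(x$cv, "family", "ME", "MSDE", "MSE", "RMSE",
                      "RMSSDE", "selected"))
  invisible(x)
}

#' Final prediction surface for a selected semivariogram
#'
#' Predicts with the selected model conditioned on *all* samples, outliers
#' included (outliers are excluded only from model fitting).
#'
#' @param selection A [select_variogram()] result.
#' @param targets Data frame of target points (`x`, `y`).
#' @return A `kriging_surface` tibble.
#' @export
predict_surface <- function(selection, targets) {
  krige(selection$model, selection$samples, targets)
}
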