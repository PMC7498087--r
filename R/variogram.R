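#' Semivariogram models
#'
#' Three isotropic semivariogram families cover the shapes used for the
#' chemical surfaces:
#' \describe{
#'   \item{exponential}{`gamma(h) = c0 + c1 * (1 - exp(-h / a))`}
#'   \item{whittle}{(Matern with smoothness 1)
#'     `gamma(h) = c0 + c1 * (1 - (h / a) * K1(h / a))`, `K1` the modified
#'     Bessel function of the second kind}
#'   \item{power}{`gamma(h) = c0 + c * h^lambda`, `0 < lambda < 2`
#'     (unbounded, no sill)}
#' }
#' `c0 >= 0` is the nugget, `c1 > 0` the partial sill, `a > 0` the range
#' parameter (meters). `log_transformed` records that the model was fitted to
#' log concentrations, so kriging predictions are back-transformed.
#'
#' @param family `"exponential"`, `"whittle"` or `"power"`.
#' @param nugget Nugget `c0 >= 0`.
#' @param psill Partial sill `c1 > 0` (exponential/whittle).
#' @param range Range parameter `a > 0` (exponential/whittle), meters.
#' @param slope Slope `c > 0` (power).
#' @param exponent Exponent `lambda` in `(0, 2)` (power).
#' @param log_transformed Logical; model fitted on the log scale.
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("exponential", "whittle", "power"),
                            nugget = 0, psill = NULL, range = NULL,
                            slope = NULL, exponent = NULL,
                            log_transformed = FALSE) {
  family <- match.arg(family)
  if (nugget < 0) abort("nugget must be >= 0")
  if (family == "power") {
    if (is.null(slope) || is.null(exponent)) {
      abort("power family needs 'slope' and 'exponent'")
    }
    if (slope <= 0) abort("slope must be > 0")
    if (exponent <= 0 || exponent >= 2) abort("exponent must be in (0, 2)")
  } else {
    if (is.null(psill) || is.null(range)) {
      abort(paste0(family, " family needs 'psill' and 'range'"))
    }
    if (psill <= 0) abort("partial sill must be > 0")
    if (range <= 0) abort("range must be > 0")
  }
  structure(
    list(family = family, nugget = nugget, psill = psill, range = range,
         slope = slope, exponent = exponent,
         log_transformed = log_transformed),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  cat("Semivariogram (", x$family, ")\n", sep = "")
  if (x$family == "power") {
    cat("  nugget =", format(x$nugget, digits = 4),
        " slope =", format(x$slope, digits = 4),
        " exponent =", format(x$exponent, digits = 4), "\n")
  } else {
    cat("  nugget =", format(x$nugget, digits = 4),
        " partial sill =", format(x$psill, digits = 4),
        " range =", format(x$range, digits = 4), "m\n")
  }
  if (isTRUE(x$log_transformed)) cat("  fitted on log scale\n")
  invisible(x)
}

#' Evaluate a semivariogram
#'
#' @param model A [variogram_model()].
#' @param h Nonnegative lag distances, meters.
#' @return `gamma(h)`, same length as `h`; `gamma(0) = nugget`.
#' @examples
#' m <- variogram_model("exponential", nugget = 0, psill = 1, range = 1)
#' semivariance(m, 1) # 1 - exp(-1)
#' @export
semivariance <- function(model, h) {
  if (any(h < 0)) abort("lag distances must be >= 0")
  dims <- dim(h)
  h <- as.numeric(h)
  g <- switch(model$family,
    exponential = model$psill * (1 - exp(-h / model$range)),
    whittle = {
      u <- h / model$range
      out <- numeric(length(u))
      pos <- u > 0
      # u * K1(u) -> 1 as u -> 0; besselK underflows for large u (gamma -> sill)
      ku <- ifelse(pos, u * suppressWarnings(besselK(pmin(u, 700), 1)), 0)
      ku[!is.finite(ku)] <- 0
      model$psill * (1 - ifelse(pos, ku, 1))
    },
    power = model$slope * h^model$exponent
  )
  out <- model$nugget + g
  # gamma(0) = nugget by convention even with a positive nugget
  out[h == 0] <- model$nugget
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' Empirical semivariogram
#'
#' Classical (Matheron) binned estimator: half the mean squared difference of
#' all sample pairs within each lag bin. Default binning is 10 equal-width
#' bins up to half the maximum pairwise distance.
#'
#' @param samples Data frame with `x`, `y` and a value column (`concentration`
#'   or `value`).
#' @param n_bins Number of lag bins.
#' @param max_lag Largest lag considered; default half the maximum pairwise
#'   distance.
#' @param log_transform Work on `log(value)`.
#' @return Tibble with `lag` (mean pair distance in bin), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(samples, n_bins = 10, max_lag = NULL,
                                log_transform = FALSE) {
  xy <- as.matrix(samples[, c("x", "y")])
  z <- sample_values(samples, log_transform)
  d <- as.matrix(dist(xy))
  iu <- upper.tri(d)
  dd <- d[iu]
  gg <- 0.5 * outer(z, z, "-")[iu]^2
  max_lag <- max_lag %||% (max(dd) / 2)
  keep <- dd <= max_lag & dd > 0
  if (!any(keep)) abort("no sample pairs within max_lag")
  dd <- dd[keep]; gg <- gg[keep]
  bin <- pmin(n_bins, 1L + floor(dd / max_lag * n_bins))
  tibble::tibble(
    lag = as.numeric(tapply(dd, bin, mean)),
    gamma = as.numeric(tapply(gg, bin, mean)),
    n_pairs = as.integer(table(bin))
  )
}

sample_values <- function(samples, log_transform) {
  vcol <- intersect(c("concentration", "value"), names(samples))[1]
  if (is.na(vcol)) abort("samples need a 'concentration' or 'value' column")
  z <- as.numeric(samples[[vcol]])
  if (log_transform) {
    if (any(z <= 0)) abort("log transform requires strictly positive values")
    z <- log(z)
  }
  z
}

#' Fit a semivariogram by weighted least squares
#'
#' Fits the chosen family to the empirical semivariogram by Cressie-style
#' weighted least squares (weights `n_pairs / gamma_model^2`), with
#' parameters optimized on unconstrained transforms (log for positive
#' parameters, sqrt for the nugget, scaled logit for the power exponent).
#'
#' @param samples Data frame with `x`, `y` and a value column.
#' @param family Semivariogram family.
#' @param log_transform Fit to log values (recorded on the model).
#' @param n_bins,max_lag Passed to [empirical_variogram()].
#' @return A [variogram_model()] with the empirical variogram attached as
#'   attribute `empirical` and the WLS objective as `objective`.
#' @export
fit_variogram <- function(samples, family = c("exponential", "whittle", "power"),
                          log_transform = FALSE, n_bins = 10, max_lag = NULL) {
  family <- match.arg(family)
  xy <- as.matrix(samples[, c("x", "y")])
  if (nrow(unique(round(xy, 9))) < 5L) {
    abort("need at least five spatially distinct samples")
  }
  emp <- empirical_variogram(samples, n_bins = n_bins, max_lag = max_lag,
                             log_transform = log_transform)
  z <- sample_values(samples, log_transform)
  s2 <- var(z)
  lag_scale <- max(emp$lag)

  build <- function(p) {
    if (family == "power") {
      variogram_model(family, nugget = p[1]^2,
                      slope = exp(p[2]), exponent = 2 * plogis(p[3]),
                      log_transformed = log_transform)
    } else {
      variogram_model(family, nugget = p[1]^2, psill = exp(p[2]),
                      range = exp(p[3]), log_transformed = log_transform)
    }
  }
  objective <- function(p) {
    m <- try(build(p), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    gm <- semivariance(m, emp$lag)
    if (any(gm <= 0)) gm <- pmax(gm, 1e-12)
    sum(emp$n_pairs * (emp$gamma - gm)^2 / gm^2)
  }
  start <- if (family == "power") {
    c(sqrt(s2 / 20), log(s2 / lag_scale), 0)
  } else {
    c(sqrt(s2 / 20), log(s2), log(lag_scale / 3))
  }
  fit <- optim(start, objective, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  model <- build(fit$par)
  attr(model, "empirical") <- emp
  attr(model, "objective") <- fit$value
  model
}
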