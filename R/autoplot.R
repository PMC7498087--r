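#' Plot a kriging surface
#'
#' @param object A `kriging_surface` from [krige()] / [predict_surface()].
#' @param what `"prediction"` or `"standard_error"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kriging_surface <- function(object, what = c("prediction",
                                                      "standard_error"),
                                     ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Plot a fitted semivariogram over its empirical points
#'
#' @param object A [fit_variogram()] result (empirical variogram attached).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variogram_model <- function(object, ...) {
  emp <- attr(object, "empirical")
  if (is.null(emp)) abort("model carries no empirical variogram (not fitted?)")
  hh <- seq(0, max(emp$lag), length.out = 200)
  curve <- tibble::tibble(lag = hh, gamma = semivariance(object, hh))
  ggplot2::ggplot(emp, ggplot2::aes(.data$lag, .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::geom_line(data = curve) +
    ggplot2::labs(x = "lag h (m)", y = expression(gamma(h)),
                  title = paste(object$family, "semivariogram")) +
    ggplot2::scale_size_continuous(name = "pairs")
}

#' Plot fitted detection functions
#'
#' Class-specific half-normal capture probability against distance from the
#' activity center (effective distance under anisotropy).
#'
#' @param object An `scr_fit`.
#' @param max_d Largest distance shown (default 3x the largest sigma).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scr_fit <- function(object, max_d = NULL, ...) {
  rp <- real_params(object)
  g0s <- rp[rp$parameter == "g0", ]
  sigs <- rp[rp$parameter == "sigma", ]
  max_d <- max_d %||% (3 * max(sigs$estimate))
  dd <- seq(0, max_d, length.out = 200)
  curves <- purrr::map_dfr(seq_len(nrow(g0s)), function(c) {
    tibble::tibble(
      class = if (nzchar(g0s$class[c])) g0s$class[c] else "all",
      d = dd,
      g = halfnormal_g(dd, g0s$estimate[c],
                       sigs$estimate[min(c, nrow(sigs))])
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$d, .data$g,
                                       color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from activity center (m)",
                  y = "capture probability g(d)", title = object$label)
}

#' Plot a fitted density surface
#'
#' @param fit An `scr_fit`.
#' @return A ggplot of `D(s)` over the mask (animals/ha).
#' @export
plot_density_surface <- function(fit) {
  dens <- predict_density(fit)
  ggplot2::ggplot(dens, ggplot2::aes(.data$x, .data$y,
                                     fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "D (animals/ha)") +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
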