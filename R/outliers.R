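#' Iterative Grubbs outlier screen
#'
#' Repeatedly computes the Grubbs statistic `G = max |x - mean| / sd`,
#' compares it with the one-outlier critical value at level `alpha`
#' (`((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`), removes the extreme value when
#' significant, and stops when none remains or fewer than three values are
#' left. Used to screen chemical concentrations before semivariogram fitting;
#' flagged values are excluded from fitting but restored as conditioning data
#' for the final prediction surfaces.
#'
#' @param values Numeric vector, at least three non-identical values.
#' @param alpha Per-step significance level.
#' @return Integer indices (into `values`) of flagged outliers, possibly
#'   empty; ordered by removal.
#' @examples
#' grubbs_iterative(c(1, 2, 3, 2, 1, 100))
#' @export
grubbs_iterative <- function(values, alpha = 0.01) {
  if (length(values) < 3L) abort("need at least three values")
  if (any(!is.finite(values))) abort("values must be finite")
  if (length(unique(values)) == 1L) {
    warn("constant vector: no outliers can be identified")
    return(integer(0))
  }
  keep <- seq_along(values)
  out <- integer(0)
  repeat {
    x <- values[keep]
    n <- length(x)
    if (n < 3L) break
    s <- sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    tcrit <- qt(1 - alpha / (2 * n), df = n - 2)
    gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g <= gcrit) break
    i <- which.max(dev)
    out <- c(out, keep[i])
    keep <- keep[-i]
  }
  out
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] returning a tidy one-row tibble;
#' used to decide whether a chemical is modeled on the log scale before
#' kriging (concentrations cannot be negative, so non-normal analytes are
#' log-transformed).
#'
#' @param values Numeric vector, 3 to 5000 non-constant values.
#' @return Tibble with columns `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3L || length(values) > 5000L) {
    abort("Shapiro-Wilk needs between 3 and 5000 values")
  }
  if (length(unique(values)) == 1L) abort("constant vector")
  st <- shapiro.test(values)
  tibble::tibble(W = unname(st$statistic), p_value = st$p.value)
}
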