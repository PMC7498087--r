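#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`, with `n` the number of
#' distinct individuals (the effective sample size of a capture-recapture
#' likelihood) and `K` the parameter count. Undefined when `n <= K + 1`.
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Effective sample size (distinct individuals).
#' @return The AICc value.
#' @examples
#' aicc(-419.0, 8, 31) # 860.5
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) abort("AICc undefined: need n > K + 1")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from AICc differences
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`.
#'
#' @param delta Vector of AICc differences from the best model.
#' @return Weights summing to 1.
#' @examples
#' akaike_weights(c(0, 3.7, 3.8, 3.9, 4.0, 4.0))[1] # ~0.58
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Rank fitted SCR models by AICc
#'
#' Builds the conventional model-selection table: models sorted by AICc with
#' differences, Akaike weights, and a `competing` flag for models within 4
#' AICc units of the best (the conservative competing-model rule used
#' throughout).
#'
#' @param fits A list of `scr_fit` objects, or a data frame with columns
#'   `model`, `logLik`, `K`, `n` (printed-table arithmetic).
#' @param delta_max Competing-model threshold on delta AICc.
#' @return Tibble: `model`, `K`, `AICc`, `dAICc`, `weight`, `logLik`,
#'   `deviance`, `competing`, sorted by AICc.
#' @export
model_table <- function(fits, delta_max = 4) {
  tab <- if (is.data.frame(fits)) {
    tib <- tibble::as_tibble(fits)
    need <- c("model", "logLik", "K", "n")
    miss <- setdiff(need, names(tib))
    if (length(miss)) {
      abort(paste0("model table input missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    dplyr::mutate(
      tib,
      AICc = purrr::pmap_dbl(list(.data$logLik, .data$K, .data$n), aicc),
      deviance = -2 * .data$logLik
    )
  } else {
    purrr::map_dfr(fits, glance)
  }
  tab <- dplyr::arrange(tab, .data$AICc)
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$weight <- akaike_weights(tab$dAICc)
  tab$competing <- tab$dAICc <= delta_max
  dplyr::select(tab, "model", "K", "AICc", "dAICc", "weight", "logLik",
                "deviance", "competing", dplyr::any_of("converged"))
}
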