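#' WHO-2005 mammalian toxic equivalency factors
#'
#' The packaged TEF lookup table (dioxin, furan and dioxin-like PCB
#' congeners; potency relative to 2,3,7,8-TCDD, whose TEF is 1). Shipped as
#' an editable CSV (`inst/extdata/tef_who2005_mammal.csv`); pass your own
#' two-column table (`congener`, `tef`) anywhere a TEF table is accepted.
#'
#' @param path Optional path to an alternative two-column CSV.
#' @return Tibble with columns `congener` and `tef`.
#' @examples
#' tef_table()
#' @export
tef_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tef_who2005_mammal.csv",
                                package = "scrsoil", mustWork = TRUE)
  tab <- read_delim_quiet(path)
  if (!all(c("congener", "tef") %in% names(tab))) {
    abort("a TEF table needs columns 'congener' and 'tef'")
  }
  if (any(tab$tef < 0)) abort("TEFs must be >= 0")
  tab
}

#' Toxic equivalents (TEQ) of a composite sample
#'
#' The TEQ of a soil sample is the TEF-weighted sum of its aryl
#' hydrocarbon-binding congener concentrations:
#' `TEQ = sum(concentration_i * TEF_i)`, in the concentration units of the
#' congeners (ppt here). Nondetect congeners enter at their detection limits
#' via the substitution convention carried on the sample records.
#'
#' @param congeners Data frame with columns `analyte` (congener name) and
#'   `concentration`; typically the congener rows of one composite sample.
#' @param tefs A TEF table from [tef_table()].
#' @return A single TEQ concentration.
#' @examples
#' compute_teq(
#'   data.frame(analyte = c("2,3,7,8-TCDD", "PCB-126"),
#'              concentration = c(10, 5)),
#'   tef_table()
#' ) # 10 * 1 + 5 * 0.1
#' @export
compute_teq <- function(congeners, tefs = tef_table()) {
  congeners <- tibble::as_tibble(congeners)
  if (!all(c("analyte", "concentration") %in% names(congeners))) {
    abort("congener table needs columns 'analyte' and 'concentration'")
  }
  i <- match(congeners$analyte, tefs$congener)
  if (anyNA(i)) {
    abort(paste0("congener(s) missing from the TEF table: ",
                 paste(unique(congeners$analyte[is.na(i)]), collapse = ", ")))
  }
  sum(congeners$concentration * tefs$tef[i])
}

#' Per-sample TEQ scores for a table of congener records
#'
#' Applies [compute_teq()] within each `sample_id`, returning soil-sample
#' records for a new analyte `"TEQ"` suitable for [screen_chemicals()].
#' The TEQ row inherits each sample's location and grid label; it is never
#' marked censored (it is a weighted sum of detects and substituted
#' nondetects, not a laboratory measurement with its own reporting limit).
#'
#' @param samples Soil-sample records ([chem_samples()]) restricted to
#'   congener analytes.
#' @param tefs A TEF table.
#' @return Tibble of TEQ sample records (one row per `sample_id`).
#' @export
teq_by_sample <- function(samples, tefs = tef_table()) {
  samples <- chem_samples(samples)
  samples |>
    dplyr::group_by(.data$sample_id, .data$grid, .data$x, .data$y) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        analyte = "TEQ",
        concentration = compute_teq(d, tefs),
        detection_limit = NA_real_,
        censored = FALSE
      )
    }) |>
    dplyr::ungroup()
}
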