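#' Trap saturation
#'
#' Average proportion of traps occupied at the end of an occasion: total
#' captures divided by (number of traps x number of occasions). Modeling
#' single-catch live traps with a multi-catch multinomial likelihood is
#' near-unbiased while saturation stays well below the ~86% threshold of
#' Efford's simulations; [fit_scr()] warns loudly past that point.
#'
#' @param captures A [capture_data()].
#' @param traps A [trap_array()].
#' @return A proportion in `[0, 1]`.
#' @examples
#' tr <- trap_array(data.frame(trap_id = c("a", "b"), x = 0:1, y = 0))
#' cd <- capture_data(
#'   data.frame(individual_id = "i1", occasion = 1, trap_id = "a"),
#'   tr, n_occasions = 5
#' )
#' trap_saturation(cd, tr) # 1 / (2 * 5)
#' @export
trap_saturation <- function(captures, traps) {
  traps <- trap_array(traps)
  if (n_occasions(captures) < 1L) abort("need at least one occasion")
  nrow(captures) / (nrow(traps) * n_occasions(captures))
}

#' Descriptive capture summary
#'
#' One-row tibble of the descriptive statistics usually reported for a
#' capture-mark-recapture survey. A recapture is any capture after an
#' individual's first; a *spatial* recapture is a recapture in a trap
#' different from that individual's first-capture trap (what identifies the
#' spatial scale sigma).
#'
#' @param captures A [capture_data()].
#' @return Tibble with columns `n_individuals`, `n_captures`, `n_recaptures`,
#'   `n_spatial_recaptures`, `mean_recaptures`, `traps_used` and a nested
#'   `species_counts` tibble (individuals and captures per species).
#' @export
capture_summary <- function(captures) {
  caps <- tibble::as_tibble(captures)
  if (!nrow(caps)) {
    return(tibble::tibble(
      n_individuals = 0L, n_captures = 0L, n_recaptures = 0L,
      n_spatial_recaptures = 0L, mean_recaptures = NaN, traps_used = 0L,
      species_counts = list(tibble::tibble(
        species = character(), n_individuals = integer(), n_captures = integer()
      ))
    ))
  }
  caps <- dplyr::arrange(caps, .data$individual_id, .data$occasion)
  per_ind <- caps |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      n_caps = dplyr::n(),
      n_spatial = sum(.data$trap_id[-1] != .data$trap_id[1]),
      .groups = "drop"
    )
  n_ind <- nrow(per_ind)
  n_cap <- nrow(caps)
  spp <- caps |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_individuals = dplyr::n_distinct(.data$individual_id),
      n_captures = dplyr::n(), .groups = "drop"
    )
  tibble::tibble(
    n_individuals = n_ind,
    n_captures = n_cap,
    n_recaptures = n_cap - n_ind,
    n_spatial_recaptures = sum(per_ind$n_spatial),
    mean_recaptures = (n_cap - n_ind) / n_ind,
    traps_used = dplyr::n_distinct(caps$trap_id),
    species_counts = list(spp)
  )
}
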