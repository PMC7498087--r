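#' Build a habitat mask (discretized state space)
#'
#' The state space S of an SCR model is the region assumed to contain every
#' activity center with non-negligible capture probability. It is discretized
#' as a regular lattice of points with a given `spacing`, keeping each point
#' whose distance to the nearest trap is at most `buffer`. The recommended
#' buffer is about three times the spatial detection scale sigma, and spacing
#' should stay below sigma to avoid discretization bias (a warning is issued
#' downstream when it does not).
#'
#' Lattice convention (fixed so point counts are bit-reproducible): points sit
#' at cell centers, with the lattice origin anchored at
#' `(min(x) - buffer, min(y) - buffer)` of the trap bounding box, i.e. the
#' i-th x coordinate is `min(x) - buffer + (i - 1/2) * spacing`.
#'
#' @param traps A [trap_array()].
#' @param buffer Buffer distance around traps, meters (> 0).
#' @param spacing Lattice spacing, meters (> 0, < buffer).
#' @param covariates Optional named list of long rasters (tibbles with
#'   `x`, `y`, `value`, e.g. from [read_asc()] or [krige()] output using
#'   `prediction` as value); each is sampled at mask points by nearest-cell
#'   lookup and stored as a mask column.
#' @return A tibble of class `habitat_mask` with columns `x`, `y` and one
#'   column per covariate; attributes `spacing` (m) and `buffer` (m).
#' @examples
#' tr <- trap_array(data.frame(trap_id = "t1", x = 0, y = 0))
#' m <- build_mask(tr, buffer = 50, spacing = 10)
#' mask_area(m) # hectares
#' @export
build_mask <- function(traps, buffer, spacing, covariates = NULL) {
  traps <- trap_array(traps)
  if (!is.finite(buffer) || buffer <= 0) abort("buffer must be > 0")
  if (!is.finite(spacing) || spacing <= 0) abort("spacing must be > 0")
  if (spacing >= buffer) {
    abort("spacing must be smaller than buffer (degenerate mask)")
  }
  x0 <- min(traps$x) - buffer
  y0 <- min(traps$y) - buffer
  nx <- ceiling((max(traps$x) + buffer - x0) / spacing)
  ny <- ceiling((max(traps$y) + buffer - y0) / spacing)
  xs <- x0 + (seq_len(nx) - 0.5) * spacing
  ys <- y0 + (seq_len(ny) - 0.5) * spacing
  pts <- tidyr::expand_grid(y = ys, x = xs)[, c("x", "y")]
  d2 <- nearest_trap_dist2(pts$x, pts$y, traps)
  mask <- pts[d2 <= buffer^2, ]
  attr(mask, "spacing") <- spacing
  attr(mask, "buffer") <- buffer
  class(mask) <- c("habitat_mask", class(tibble::tibble()))
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      mask <- add_mask_covariate(mask, covariates[[nm]], nm)
    }
  }
  mask
}

# squared distance from each point to its nearest trap, blocked to bound memory
nearest_trap_dist2 <- function(px, py, traps) {
  n <- length(px)
  out <- numeric(n)
  block <- 20000L
  for (i0 in seq(1L, n, by = block)) {
    idx <- i0:min(i0 + block - 1L, n)
    dx <- outer(px[idx], traps$x, "-")
    dy <- outer(py[idx], traps$y, "-")
    out[idx] <- .rowMin(dx * dx + dy * dy)
  }
  out
}

.rowMin <- function(m) do.call(pmin, as.data.frame(m))

#' @rdname build_mask
#' @param mask A `habitat_mask`.
#' @export
mask_area <- function(mask) {
  sp <- attr(mask, "spacing") %||% abort("mask carries no spacing attribute")
  nrow(mask) * sp^2 / 1e4 # hectares
}

#' @rdname build_mask
#' @export
mask_spacing <- function(mask) {
  attr(mask, "spacing") %||% abort("mask carries no spacing attribute")
}

#' Attach a covariate surface to a habitat mask
#'
#' Values are sampled at mask point centers by nearest-cell lookup (no
#' interpolation): mask spacing is at or below the resolution of the rasters
#' used here, so interpolation would add nothing.
#'
#' @param mask A `habitat_mask`.
#' @param surface Long raster tibble with `x`, `y` and a value column (named
#'   `value` or `prediction`).
#' @param name Column name for the covariate on the mask.
#' @return The mask with one extra column.
#' @export
add_mask_covariate <- function(mask, surface, name) {
  vcol <- intersect(c("value", "prediction"), names(surface))[1]
  if (is.na(vcol)) abort("surface must have a 'value' or 'prediction' column")
  if (!nrow(surface)) abort("empty covariate surface")
  sp <- attr(mask, "spacing"); bf <- attr(mask, "buffer"); cl <- class(mask)
  idx <- vapply(seq_len(nrow(mask)), function(i) {
    which.min((surface$x - mask$x[i])^2 + (surface$y - mask$y[i])^2)
  }, 1L)
  vals <- surface[[vcol]][idx]
  if (any(!is.finite(vals))) {
    abort(paste0("covariate '", name, "' is not finite at ",
                 sum(!is.finite(vals)), " mask point(s)"))
  }
  mask[[name]] <- vals
  attr(mask, "spacing") <- sp
  attr(mask, "buffer") <- bf
  class(mask) <- cl
  mask
}
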