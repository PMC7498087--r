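#' Anisotropic effective distance
#'
#' Home ranges elongated along a fixed landscape axis (a canyon here) violate
#' the circular-home-range assumption of isotropic SCR detection. The
#' displacement between activity center and trap is rotated into the
#' (major, minor) frame of the anisotropy axis and the minor component is
#' scaled by the ratio `phi_r`:
#' `u = cos(phi_a) dx + sin(phi_a) dy`,
#' `v = -sin(phi_a) dx + cos(phi_a) dy`,
#' `d_eff = sqrt(u^2 + (phi_r v)^2)`.
#' Detection range along the axis `phi_a` is therefore `phi_r` times the
#' perpendicular range; `phi_r = 1` recovers the Euclidean distance.
#'
#' @param dx,dy Displacement components, meters (trap minus center).
#' @param phi_a Anisotropy axis, radians counterclockwise from the x axis
#'   (fixed from landscape orientation, not estimated).
#' @param phi_r Anisotropy ratio (> 0; values above 1 elongate detection
#'   along the axis).
#' @return Effective distances, meters.
#' @examples
#' aniso_transform(0, 1, phi_a = 0, phi_r = 2) # 2
#' aniso_transform(1, 0, phi_a = 0, phi_r = 2) # 1
#' @export
aniso_transform <- function(dx, dy, phi_a, phi_r) {
  u <- cos(phi_a) * dx + sin(phi_a) * dy
  v <- -sin(phi_a) * dx + cos(phi_a) * dy
  sqrt(u^2 + (phi_r * v)^2)
}

#' Half-normal detection function
#'
#' Capture probability as a function of the distance `d` between a trap and
#' an animal's activity center: `g(d) = g0 * exp(-d^2 / (2 sigma^2))`.
#' `g0` is the capture probability for a trap at the activity center and
#' `sigma` (meters) sets how fast probability decays with distance.
#'
#' @param d Distance(s), meters, `>= 0`.
#' @param g0 Capture probability at distance zero, in (0, 1).
#' @param sigma Spatial scale, meters.
#' @return Capture probabilities.
#' @examples
#' halfnormal_g(0, 0.31, 14)                       # g0
#' halfnormal_g(14 * sqrt(2 * log(2)), 0.31, 14)   # g0 / 2
#' @export
halfnormal_g <- function(d, g0, sigma) {
  if (any(d < 0)) abort("distances must be >= 0")
  g0 * exp(-d^2 / (2 * sigma^2))
}

#' Multi-catch multinomial cell probabilities
#'
#' With several traps competing for one animal in an occasion, per-trap
#' capture probabilities are combined through competing hazards:
#' `h_k = -log(1 - g_k)`, `H = sum(h_k)`, the animal escapes capture with
#' `p_0 = exp(-H)` and is taken by trap k with
#' `p_k = (h_k / H) (1 - exp(-H))`. The cells close: `p_0 + sum(p_k) = 1`.
#'
#' @param g Per-trap capture probabilities in `[0, 1)` (from
#'   [halfnormal_g()] over [aniso_transform()] distances, with any
#'   behavioral or group adjustment already applied on the logit scale).
#' @return Tibble with `trap` (0 = not captured) and `prob`.
#' @export
multicatch_probs <- function(g) {
  if (any(g < 0) || any(g >= 1)) {
    abort("per-trap capture probabilities must lie in [0, 1) (g = 1 gives an infinite hazard)")
  }
  h <- -log1p(-g)
  H <- sum(h)
  if (H == 0) {
    probs <- c(1, rep(0, length(g)))
  } else {
    pk <- (h / H) * (-expm1(-H))
    probs <- c(exp(-H), pk)
  }
  tibble::tibble(trap = seq_along(probs) - 1L, prob = probs)
}
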