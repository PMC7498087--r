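#' Specify an SCR model
#'
#' Model structure is given by three one-sided formulas plus an anisotropy
#' switch, mirroring the conventional SCR notation
#' `D(~1) g0(~bk + mix) sigma(~mix)`:
#' \describe{
#'   \item{`D`}{`~1` for homogeneous density, or `~cov1 + cov2` for a
#'     log-linear inhomogeneous Poisson density over mask covariates
#'     (`D(s) = exp(beta0 + sum beta_j z_j(s))`, animals per hectare).}
#'   \item{`g0`}{any of `bk` (trap-specific learned behavioral response on
#'     the logit of g0), `sex`, `species` (grouping offsets), `mix` (latent
#'     two-class finite mixture).}
#'   \item{`sigma`}{any of `sex`, `species`, `mix`, as log-scale offsets.}
#' }
#' At most one class dimension (`sex`, `species` or `mix`) may appear across
#' `g0` and `sigma`; its class proportions are estimated on the multinomial
#' logit scale, with known sex/species memberships entering the likelihood
#' directly and unknowns marginalized (a hybrid mixture). Links: logit for
#' `g0` and mixing proportions, log for `sigma`, density and the anisotropy
#' ratio.
#'
#' @param D,g0,sigma One-sided formulas (see above).
#' @param anisotropy Logical; apply [aniso_transform()] with fixed axis
#'   `phi_a` and an estimated ratio `phi_r`.
#' @param phi_a Anisotropy axis, radians (default 1.8326 = 105 degrees,
#'   never estimated).
#' @return An object of class `scr_model_spec`.
#' @examples
#' scr_model_spec(D = ~1, g0 = ~bk + mix, sigma = ~mix, anisotropy = TRUE)
#' @export
scr_model_spec <- function(D = ~1, g0 = ~1, sigma = ~1, anisotropy = FALSE,
                           phi_a = 1.8326) {
  g0_terms <- formula_terms(g0)
  sig_terms <- formula_terms(sigma)
  d_covs <- formula_terms(D)
  bad <- setdiff(g0_terms, c("bk", "sex", "species", "mix"))
  if (length(bad)) {
    abort(paste0("unsupported g0 term(s): ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(sig_terms, c("sex", "species", "mix"))
  if (length(bad)) {
    abort(paste0("unsupported sigma term(s): ", paste(bad, collapse = ", ")))
  }
  class_terms <- intersect(union(g0_terms, sig_terms),
                           c("sex", "species", "mix"))
  if (length(class_terms) > 1L) {
    abort("at most one class dimension (sex, species or mix) per model")
  }
  class_var <- if (length(class_terms)) class_terms else NULL
  structure(
    list(
      d_covs = d_covs,
      g0_bk = "bk" %in% g0_terms,
      g0_class = !is.null(class_var) && class_var %in% g0_terms,
      sigma_class = !is.null(class_var) && class_var %in% sig_terms,
      class_var = class_var,
      anisotropy = isTRUE(anisotropy),
      phi_a = phi_a
    ),
    class = "scr_model_spec"
  )
}

formula_terms <- function(f) {
  if (!inherits(f, "formula")) abort("model terms must be one-sided formulas")
  attr(stats::terms(f), "term.labels")
}

#' @export
print.scr_model_spec <- function(x, ...) {
  cat(model_label(x), "\n")
  invisible(x)
}

#' Human-readable model label
#'
#' @param spec An [scr_model_spec()].
#' @return Character label like `"D(~1) g0(~bk + mix) sigma(~mix) aniso"`.
#' @export
model_label <- function(spec) {
  show <- function(v) if (length(v)) paste(v, collapse = " + ") else "1"
  g0_terms <- c(if (spec$g0_bk) "bk",
                if (spec$g0_class) spec$class_var)
  sig_terms <- if (spec$sigma_class) spec$class_var
  paste0(
    "D(~", show(spec$d_covs), ") g0(~", show(g0_terms), ") sigma(~",
    show(sig_terms), ")", if (spec$anisotropy) " aniso" else ""
  )
}

# Class structure implied by a spec for a given data set: levels, and each
# individual's known class index (NA = latent, marginalized over psi).
spec_classes <- function(spec, captures) {
  if (is.null(spec$class_var)) {
    return(list(levels = "all", known = rep(1L, dplyr::n_distinct(
      tibble::as_tibble(captures)$individual_id))))
  }
  caps <- tibble::as_tibble(captures)
  ind <- caps[!duplicated(caps$individual_id), , drop = FALSE]
  ind <- ind[order(ind$individual_id), ]
  if (spec$class_var == "mix") {
    return(list(levels = c("class1", "class2"),
                known = rep(NA_integer_, nrow(ind))))
  }
  lab <- ind[[spec$class_var]]
  levels <- sort(unique(lab[lab != "unknown"]))
  if (length(levels) < 2L) {
    abort(paste0("grouping covariate '", spec$class_var,
                 "' needs at least two observed levels"))
  }
  known <- match(lab, levels) # NA for "unknown" -> marginalized
  list(levels = levels, known = known)
}

#' Named parameter template for a model specification
#'
#' Zero-filled named vector on the link scale in the canonical order used by
#' [scr_loglik()] and [fit_scr()]: density intercept and covariate
#' coefficients, `g0` intercept (logit), behavioral and class offsets,
#' `sigma` intercept (log) and class offsets, mixing logits, `log(phi_r)`.
#'
#' @inheritParams scr_loglik
#' @return Named numeric vector of zeros.
#' @export
scr_par_template <- function(spec, captures) {
  cls <- spec_classes(spec, captures)
  n_cl <- length(cls$levels)
  nm <- c(
    "D.(Intercept)",
    if (length(spec$d_covs)) paste0("D.", spec$d_covs),
    "g0.(Intercept)",
    if (spec$g0_bk) "g0.bk",
    if (spec$g0_class && n_cl > 1)
      paste0("g0.", spec$class_var, cls$levels[-1]),
    "sigma.(Intercept)",
    if (spec$sigma_class && n_cl > 1)
      paste0("sigma.", spec$class_var, cls$levels[-1]),
    if (!is.null(spec$class_var) && n_cl > 1)
      paste0("psi.", cls$levels[-1]),
    if (spec$anisotropy) "log(phi_r)"
  )
  setNames(numeric(length(nm)), nm)
}
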