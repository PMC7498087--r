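#' Run the full soil-to-density analysis pipeline
#'
#' Orchestrates every stage from one configuration: (1) load or simulate
#' inputs; (2) screen analytes for among-grid differences
#' ([screen_chemicals()]) -- only analytes with a spatial signal are worth
#' interpolating; (3) per retained analyte, select a semivariogram by
#' cross-validation and krige its surface onto the habitat mask
#' ([select_variogram()], [predict_surface()]); (4) fit the homogeneous-
#' density detection model set; (5) retain the detection terms whose 95%
#' CIs exclude zero (the homogeneous-to-inhomogeneous handoff rule; AICc is
#' *not* used for this step) and carry anisotropy over from the best
#' homogeneous model; (6) fit one inhomogeneous log-linear density model
#' per kriged analyte with exactly those detection terms; (7) rank all
#' models by AICc with the delta <= 4 competing rule. Inhomogeneous density
#' models are a priori hypothesis models: they stay in the report flagged
#' as such even when their chemical coefficient is uninformative.
#'
#' @param config Named list (or path to a `key = value` file read by
#'   [read_config()], for file-based runs): `traps_file`, `captures_file`,
#'   `samples_file`, `n_occasions`, `buffer` (default 200 m),
#'   `mask_spacing` (default 10 m), `alpha` (screen level, 0.05),
#'   `families` (semivariogram candidates), `detection_specs` (list of
#'   [scr_model_spec()]; a compact default set otherwise), `anisotropy`
#'   (default for the built-in detection set), `n_starts`, `delta_max`,
#'   `simulate` (a [sim_config()] list to generate inputs instead of
#'   reading files), `verbose`.
#' @param data Optional list with `traps`, `captures`, `samples` already in
#'   memory (overrides files).
#' @param seed Integer seed stamped into the manifest and driving any
#'   simulation.
#' @return A `pipeline_report` list: `screened`, `cv`, `surfaces`,
#'   `detection_fits`, `retained_terms`, `fits`, `model_table`, `top`,
#'   `density`, `abundance`, `manifest`.
#' @export
run_pipeline <- function(config = list(), data = NULL, seed = 1) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  verbose <- isTRUE(cfg$verbose)
  say <- function(...) if (verbose) message("[scrsoil] ", ...)
  stage <- "setup"
  fail <- function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  }
  withCallingHandlers({
    stage <- "inputs"
    if (is.null(data)) {
      if (!is.null(cfg$simulate)) {
        say("simulating survey (seed ", seed, ")")
        data <- simulate_survey(cfg$simulate, seed = seed)
      } else {
        for (f in c("traps_file", "captures_file", "samples_file")) {
          if (is.null(cfg[[f]])) abort(paste0("config lacks '", f, "'"))
          if (!file.exists(cfg[[f]])) {
            abort(paste0("missing input file: ", cfg[[f]]))
          }
        }
        traps <- read_traps(cfg$traps_file)
        data <- list(
          traps = traps,
          captures = read_captures(cfg$captures_file, traps,
                                   n_occasions = cfg$n_occasions),
          samples = read_samples(cfg$samples_file)
        )
      }
    }
    traps <- trap_array(data$traps)
    captures <- data$captures
    samples <- data$samples

    stage <- "mask"
    buffer <- cfg$buffer %||% 200
    spacing <- cfg$mask_spacing %||% 10
    mask <- data$mask %||% build_mask(traps, buffer, spacing)
    say("mask: ", nrow(mask), " points, ", round(mask_area(mask), 1), " ha")

    stage <- "soil screen"
    alpha <- cfg$alpha %||% 0.05
    screened <- screen_chemicals(samples, alpha = alpha,
                                 seed = seed)
    retained_analytes <- screened$analyte[screened$retained]
    say("analytes retained: ",
        paste(retained_analytes, collapse = ", ") %||% "none")

    stage <- "kriging"
    families <- cfg$families %||% c("exponential", "whittle", "power")
    surfaces <- list()
    cv_rows <- list()
    for (an in retained_analytes) {
      sel <- select_variogram(samples[samples$analyte == an, ],
                              families = families)
      surfaces[[an]] <- predict_surface(sel, mask[, c("x", "y")])
      cv_rows[[an]] <- dplyr::mutate(sel$cv, analyte = an,
                                     log_transformed = sel$log_transformed)
      mask <- add_mask_covariate(mask, surfaces[[an]], an)
    }
    cv <- if (length(cv_rows)) {
      dplyr::relocate(dplyr::bind_rows(cv_rows), "analyte")
    } else tibble::tibble()

    stage <- "homogeneous detection models"
    det_specs <- cfg$detection_specs %||% default_detection_specs(
      anisotropy = isTRUE(cfg$anisotropy))
    n_starts <- cfg$n_starts %||% 3
    det_fits <- purrr::map(det_specs, function(sp) {
      say("fitting ", model_label(sp))
      fit_scr(captures, traps, mask, sp, n_starts = n_starts)
    })

    stage <- "detection-term retention"
    retained <- retained_detection_terms(det_fits)
    best_hom <- det_fits[[which.min(purrr::map_dbl(det_fits, "aicc"))]]
    say("retained detection terms: ",
        paste(retained, collapse = ", ") %||% "none")

    stage <- "inhomogeneous density models"
    inhom_fits <- purrr::map(retained_analytes, function(an) {
      sp <- spec_from_terms(retained, d_cov = an,
                            anisotropy = best_hom$spec$anisotropy,
                            phi_a = best_hom$spec$phi_a)
      say("fitting ", model_label(sp))
      fit_scr(captures, traps, mask, sp, n_starts = n_starts)
    })
    names(inhom_fits) <- retained_analytes

    stage <- "model selection"
    all_fits <- c(det_fits, inhom_fits)
    tab <- model_table(all_fits, delta_max = cfg$delta_max %||% 4)
    tab$hypothesis <- tab$model %in%
      purrr::map_chr(inhom_fits, "label")
    top <- all_fits[[which.min(purrr::map_dbl(all_fits, "aicc"))]]

    report <- structure(
      list(
        screened = screened, cv = cv, surfaces = surfaces,
        detection_fits = det_fits, retained_terms = retained,
        fits = all_fits, model_table = tab, top = top,
        density = real_params(top)[real_params(top)$parameter == "D", ],
        abundance = derived_abundance(top),
        mask = mask,
        manifest = list(
          seed = seed, config = cfg,
          package_version = as.character(utils::packageVersion("scrsoil")),
          r_version = R.version.string
        )
      ),
      class = "pipeline_report"
    )
    report
  }, error = fail)
}

# Compact default homogeneous-density model set: null, behavioral response,
# and the two-class mixture structure, each candidate term identifiable from
# its own fit.
default_detection_specs <- function(anisotropy = FALSE) {
  list(
    scr_model_spec(D = ~1, g0 = ~1, sigma = ~1, anisotropy = anisotropy),
    scr_model_spec(D = ~1, g0 = ~bk, sigma = ~1, anisotropy = anisotropy),
    scr_model_spec(D = ~1, g0 = ~bk + mix, sigma = ~mix,
                   anisotropy = anisotropy)
  )
}

# Terms whose 95% CI excludes zero in any homogeneous fit containing them.
retained_detection_terms <- function(fits) {
  hits <- character(0)
  for (f in fits) {
    td <- tidy(f)
    ci_excl <- !is.na(td$lcl) & (td$lcl > 0 | td$ucl < 0)
    if (f$spec$g0_bk && any(ci_excl[td$term == "g0.bk"])) {
      hits <- c(hits, "bk")
    }
    if (f$spec$g0_class &&
        any(ci_excl[grepl("^g0\\.(mix|sex|species)", td$term)])) {
      hits <- c(hits, "mix_g0")
    }
    if (f$spec$sigma_class &&
        any(ci_excl[grepl("^sigma\\.(mix|sex|species)", td$term)])) {
      hits <- c(hits, "mix_sigma")
    }
  }
  unique(hits)
}

spec_from_terms <- function(terms, d_cov, anisotropy, phi_a) {
  g0_rhs <- c(if ("bk" %in% terms) "bk", if ("mix_g0" %in% terms) "mix")
  sig_rhs <- if ("mix_sigma" %in% terms) "mix"
  mk <- function(v) {
    stats::as.formula(paste("~", if (length(v)) paste(v, collapse = "+")
                            else "1"))
  }
  scr_model_spec(D = mk(d_cov), g0 = mk(g0_rhs), sigma = mk(sig_rhs),
                 anisotropy = anisotropy, phi_a = phi_a)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("scrsoil pipeline report (seed ", x$manifest$seed, ")\n", sep = "")
  cat("\nAnalyte screen:\n")
  print(dplyr::select(x$screened, "analyte", "method", "p_value", "retained"))
  if (nrow(x$cv)) {
    cat("\nSemivariogram cross-validation (selected rows):\n")
    print(dplyr::filter(x$cv, .data$selected))
  }
  cat("\nModel selection:\n")
  print(x$model_table)
  cat("\nTop model density (animals/ha) and abundance:\n")
  print(x$density)
  print(x$abundance)
  invisible(x)
}
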