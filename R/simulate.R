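#' Default simulation configuration
#'
#' Returns the parameter list used by [simulate_survey()]. The defaults are
#' the study conditions this package is designed around: three 5 x 20
#' trapping grids at 4.55 m spacing with grid centers ~170 m apart along a
#' canyon axis of 105 degrees (1.8326 rad), staggered across the canyon
#' floor; five occasions of single-catch trapping; a Peromyscus-like
#' community at 2.88 animals/ha with two latent detection classes
#' (29% with g0 = 0.04 and sigma = 71 m, 71% with g0 = 0.31 and
#' sigma = 14 m), a trap-learned behavioral response of +2.0 on logit(g0),
#' and home ranges elongated 1.7:1 along the canyon. Chemical fields emulate
#' spatially autocorrelated (lognormal where appropriate) concentration
#' surfaces with a canyon-axis trend and laboratory detection limits.
#'
#' @param ... Named overrides merged over the defaults (one level deep).
#' @return A named list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # survey geometry
    n_grids = 3, n_rows = 5, n_cols = 20, trap_spacing = 4.55,
    center_spacing = 170, lateral_offsets = c(0, 170, 55),
    axis = 1.8326, n_occasions = 5, mode = "single",
    # state space
    buffer = 200, mask_spacing = 10,
    # population
    density = 2.88, d_covs = NULL, d_betas = NULL,
    sex_ratio = 20 / 31,
    species_probs = c(boylii = 17 / 31, maniculatus = 4 / 31,
                      truei = 10 / 31),
    # detection (two latent classes)
    pi_class = c(0.29, 0.71), g0 = c(0.04, 0.31), sigma = c(71, 14),
    beta_bk = 2.0, phi_r = 1.7,
    # chemical fields: list(analyte = list(...)) on a coarse raster
    field_spacing = 20,
    analytes = list(
      Hg = list(mean = -3.2, sill = 0.5, range = 120, trend = -0.004,
                lognormal = TRUE, detection_limit = 0.02),
      Mn = list(mean = 400, sill = 4000, range = 150, trend = 0.15,
                lognormal = FALSE, detection_limit = 0),
      PCB = list(mean = -4.5, sill = 0.8, range = 100, trend = -0.005,
                 lognormal = TRUE, detection_limit = 0.005)
    ),
    n_subgrids = 6, points_per_composite = 5, composite_noise = 0.05
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Trap layout generator
#'
#' Builds `n_grids` rectangular grids of `n_rows` x `n_cols` traps at
#' `trap_spacing` meters, grid centers `center_spacing` meters apart along
#' the canyon axis with perpendicular stagger `lateral_offsets`, the whole
#' layout rotated so its long axis lies along `axis` radians. Grid geometry
#' (for subgrid-based soil sampling) is attached as attribute `grids`.
#'
#' @param n_grids,n_rows,n_cols,trap_spacing,center_spacing,lateral_offsets,axis
#'   See [sim_config()].
#' @return A [trap_array()] with a `grid` column.
#' @export
sim_trap_grids <- function(n_grids = 3, n_rows = 5, n_cols = 20,
                           trap_spacing = 4.55, center_spacing = 170,
                           lateral_offsets = c(0, 170, 55), axis = 1.8326) {
  lateral_offsets <- rep_len(lateral_offsets, n_grids)
  w <- (n_cols - 1) * trap_spacing
  h <- (n_rows - 1) * trap_spacing
  rot <- matrix(c(cos(axis), sin(axis), -sin(axis), cos(axis)), 2, 2)
  pieces <- vector("list", n_grids)
  grids <- vector("list", n_grids)
  for (g in seq_len(n_grids)) {
    cx <- (g - 1) * center_spacing          # along-canyon center
    cy <- lateral_offsets[g]                # cross-canyon stagger
    gx <- cx - w / 2 + (seq_len(n_cols) - 1) * trap_spacing
    gy <- cy - h / 2 + (seq_len(n_rows) - 1) * trap_spacing
    local <- as.matrix(tidyr::expand_grid(ly = gy, lx = gx)[, c("lx", "ly")])
    world <- local %*% t(rot)
    pieces[[g]] <- tibble::tibble(
      trap_id = sprintf("g%d_t%03d", g, seq_len(nrow(world))),
      x = world[, 1], y = world[, 2], grid = paste0("grid", g)
    )
    grids[[g]] <- tibble::tibble(grid = paste0("grid", g), cx = cx, cy = cy,
                                 width = w, height = h)
  }
  out <- trap_array(dplyr::bind_rows(pieces))
  attr(out, "grids") <- dplyr::bind_rows(grids)
  attr(out, "axis") <- axis
  out
}

#' Simulate a spatially autocorrelated chemical field
#'
#' Draws a Gaussian random field at the supplied points by Cholesky
#' factorization of the exact covariance (exponential or Whittle family,
#' `cov(h) = sill * rho(h/range)`), optionally adds a linear trend along the
#' canyon axis, and optionally exponentiates for lognormal concentrations.
#' Exact simulation is tractable because the rasters involved are desk-scale
#' (thousands of cells).
#'
#' @param points Tibble with `x`, `y` (e.g. a coarse raster or mask).
#' @param mean Field mean (log-scale mean when `lognormal`).
#' @param sill Marginal variance of the Gaussian field (0 gives a constant
#'   field).
#' @param range Correlation range parameter, meters.
#' @param family `"exponential"` or `"whittle"`.
#' @param nugget Added white-noise variance.
#' @param trend Linear trend per meter along `axis` (applied to the Gaussian
#'   field before exponentiation).
#' @param axis Trend axis, radians.
#' @param lognormal Exponentiate the field.
#' @param seed Optional integer seed.
#' @return `points` with a `value` column.
#' @export
simulate_field <- function(points, mean = 0, sill = 1, range = 100,
                           family = c("exponential", "whittle"), nugget = 0,
                           trend = 0, axis = 1.8326, lognormal = FALSE,
                           seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points)
  z <- if (sill > 0) {
    d <- as.matrix(dist(as.matrix(points[, c("x", "y")])))
    u <- d / range
    C <- switch(family,
      exponential = sill * exp(-u),
      whittle = {
        ku <- u * suppressWarnings(besselK(pmin(u, 700), 1))
        ku[!is.finite(ku)] <- 0
        ku[u == 0] <- 1
        sill * ku
      }
    )
    C <- C + diag(nugget + 1e-8 * sill, n)
    L <- tryCatch(chol(C), error = function(e) {
      abort("covariance not positive definite even after jitter")
    })
    as.numeric(crossprod(L, rnorm(n)))
  } else {
    rep(0, n)
  }
  along <- cos(axis) * points$x + sin(axis) * points$y
  field <- mean + trend * along + z
  points$value <- if (lognormal) exp(field) else field
  points
}

#' Simulate composite soil samples from a field
#'
#' Emulates the field protocol: each trapping grid is split into
#' `n_subgrids` equal subgrids (along its long axis), `points_per_composite`
#' random locations are drawn inside each subgrid, the field value is read
#' at the nearest field cell for each, and the composite concentration is
#' their average times a lognormal measurement-noise factor. Values at or
#' below the detection limit are reported *at* the detection limit and
#' flagged censored.
#'
#' @param field A [simulate_field()] result.
#' @param traps A [sim_trap_grids()] layout (for grid geometry).
#' @param analyte Analyte name for the records.
#' @param detection_limit Censoring threshold (0 = no censoring).
#' @param n_subgrids,points_per_composite See [sim_config()].
#' @param noise_sd Lognormal measurement noise (sd of log factor).
#' @param seed Optional integer seed.
#' @return A [chem_samples()] tibble.
#' @export
simulate_soil_samples <- function(field, traps, analyte = "chem",
                                  detection_limit = 0, n_subgrids = 6,
                                  points_per_composite = 5, noise_sd = 0.05,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grids <- attr(traps, "grids") %||%
    abort("traps must come from sim_trap_grids() (grid geometry needed)")
  axis <- attr(traps, "axis") %||% 0
  rot <- matrix(c(cos(axis), sin(axis), -sin(axis), cos(axis)), 2, 2)
  out <- purrr::map_dfr(seq_len(nrow(grids)), function(gi) {
    gg <- grids[gi, ]
    # subgrids split the long axis into n_subgrids equal slices
    edges <- seq(-gg$width / 2, gg$width / 2, length.out = n_subgrids + 1)
    purrr::map_dfr(seq_len(n_subgrids), function(si) {
      lx <- runif(points_per_composite, edges[si], edges[si + 1]) + gg$cx
      ly <- runif(points_per_composite, -gg$height / 2, gg$height / 2) + gg$cy
      world <- cbind(lx, ly) %*% t(rot)
      vals <- vapply(seq_len(nrow(world)), function(j) {
        field$value[which.min((field$x - world[j, 1])^2 +
                                (field$y - world[j, 2])^2)]
      }, 0)
      conc <- mean(vals) * exp(rnorm(1, 0, noise_sd))
      cens <- conc <= detection_limit
      tibble::tibble(
        sample_id = sprintf("%s_%s_s%d", analyte, gg$grid, si),
        grid = gg$grid,
        x = mean(world[, 1]), y = mean(world[, 2]),
        analyte = analyte,
        concentration = if (cens) detection_limit else conc,
        detection_limit = if (detection_limit > 0) detection_limit else NA_real_,
        censored = cens
      )
    })
  })
  chem_samples(out)
}

#' Simulate activity centers from a (in)homogeneous Poisson density
#'
#' `N ~ Poisson(sum_s D(s) * cellarea)`; centers fall in mask cells with
#' probability proportional to `D(s)` and uniform jitter within the cell
#' (equivalent to thinning a fine Poisson process). Sex, species, and latent
#' detection class are assigned independently with the configured
#' proportions.
#'
#' @param mask A [build_mask()] mask carrying any density covariates.
#' @param density Baseline density, animals/ha (`exp(beta0)`).
#' @param d_covs,d_betas Optional covariate names (mask columns) and
#'   log-linear coefficients.
#' @param sex_ratio Proportion male.
#' @param species_probs Named species proportions.
#' @param pi_class Latent detection-class proportions (length 2).
#' @param seed Optional integer seed.
#' @return Tibble: `x`, `y`, `sex`, `species`, `class`.
#' @export
simulate_population <- function(mask, density = 2.88, d_covs = NULL,
                                d_betas = NULL, sex_ratio = 0.5,
                                species_probs = c(sp1 = 1),
                                pi_class = c(0.29, 0.71), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- mask_spacing(mask)^2 / 1e4
  logd <- log(density)
  D_s <- rep(exp(logd), nrow(mask))
  if (length(d_covs)) {
    Z <- as.matrix(tibble::as_tibble(mask)[, d_covs, drop = FALSE])
    D_s <- exp(logd + drop(Z %*% d_betas))
  }
  if (any(!is.finite(D_s))) abort("density not finite over the mask")
  mu <- sum(D_s * a)
  if (mu > 1e6) abort("expected population size exceeds 1e6; check config")
  N <- rpois(1, mu)
  half <- mask_spacing(mask) / 2
  idx <- sample.int(nrow(mask), N, replace = TRUE, prob = D_s)
  tibble::tibble(
    x = mask$x[idx] + runif(N, -half, half),
    y = mask$y[idx] + runif(N, -half, half),
    sex = c("F", "M")[1L + (runif(N) < sex_ratio)],
    species = if (length(species_probs) == 1L) {
      rep(names(species_probs), N)
    } else {
      sample(names(species_probs), N, replace = TRUE, prob = species_probs)
    },
    class = 1L + (runif(N) >= pi_class[1])
  )
}

#' Simulate occasion-by-occasion capture histories
#'
#' Multi-catch mode: each animal independently draws its outcome (escape or
#' one trap) from the [multicatch_probs()] cells given its class and
#' behavioral context. Single-catch mode: competing exponential event times
#' across all free animal x trap pairs within the occasion; the earliest
#' event claims both the animal and the trap (the mechanism real Sherman
#' traps impose). Behavioral (bk) indicators update between occasions.
#'
#' @param population A [simulate_population()] tibble.
#' @param traps A [trap_array()].
#' @param n_occasions Number of occasions.
#' @param g0,sigma Class-specific detection parameters (recycled over
#'   classes).
#' @param beta_bk Behavioral-response coefficient on logit(g0).
#' @param phi_a,phi_r Anisotropy axis (radians) and ratio.
#' @param mode `"single"` or `"multi"`.
#' @param seed Optional integer seed.
#' @return A [capture_data()].
#' @export
simulate_captures <- function(population, traps, n_occasions = 5,
                              g0 = c(0.04, 0.31), sigma = c(71, 14),
                              beta_bk = 0, phi_a = 1.8326, phi_r = 1,
                              mode = c("single", "multi"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  traps <- trap_array(traps)
  N <- nrow(population)
  Ktr <- nrow(traps)
  if (N == 0) {
    return(capture_data(
      tibble::tibble(individual_id = character(), occasion = integer(),
                     trap_id = character()),
      traps, n_occasions = n_occasions
    ))
  }
  cls <- population$class %||% rep(1L, N)
  g0 <- rep_len(g0, max(cls))
  sigma <- rep_len(sigma, max(cls))
  dx <- outer(traps$x, population$x, "-")
  dy <- outer(traps$y, population$y, "-")
  d_eff <- aniso_transform(dx, dy, phi_a, phi_r) # traps x animals
  decay <- exp(-sweep(d_eff^2, 2, 2 * sigma[cls]^2, "/"))

  bk <- matrix(FALSE, Ktr, N)
  any_bk <- FALSE
  ev_animal <- ev_occasion <- ev_trap <- integer(0)
  for (t in seq_len(n_occasions)) {
    g <- if (beta_bk != 0 && any_bk) {
      plogis(qlogis(g0[cls])[col(decay)] + beta_bk * bk) * decay
    } else {
      decay * rep(g0[cls], each = Ktr)
    }
    occ_animal <- occ_trap <- integer(0)
    if (mode == "multi") {
      h <- -log1p(-g)
      H <- colSums(h)
      p0 <- exp(-H)
      caught <- which(runif(N) >= p0)
      if (length(caught)) {
        occ_animal <- caught
        occ_trap <- vapply(caught, function(i) {
          sample.int(Ktr, 1L, prob = h[, i])
        }, 1L)
      }
    } else {
      h <- -log1p(-g)
      live <- which(h > 1e-300, arr.ind = TRUE)
      if (nrow(live)) {
        tt <- rexp(nrow(live), rate = h[live])
        ord <- order(tt)
        trap_free <- rep(TRUE, Ktr)
        animal_free <- rep(TRUE, N)
        for (j in ord) {
          if (tt[j] > 1) break # occasion over
          k <- live[j, 1]; i <- live[j, 2]
          if (trap_free[k] && animal_free[i]) {
            trap_free[k] <- FALSE
            animal_free[i] <- FALSE
            occ_animal <- c(occ_animal, i)
            occ_trap <- c(occ_trap, k)
          }
        }
      }
    }
    if (length(occ_animal)) {
      ev_animal <- c(ev_animal, occ_animal)
      ev_occasion <- c(ev_occasion, rep(t, length(occ_animal)))
      ev_trap <- c(ev_trap, occ_trap)
      bk[cbind(occ_trap, occ_animal)] <- TRUE
      any_bk <- TRUE
    }
  }
  if (!length(ev_animal)) {
    return(capture_data(
      tibble::tibble(individual_id = character(), occasion = integer(),
                     trap_id = character()),
      traps, n_occasions = n_occasions
    ))
  }
  events <- tibble::tibble(animal = ev_animal, occasion = ev_occasion,
                           trap = ev_trap)
  capture_data(
    tibble::tibble(
      individual_id = sprintf("ind%04d", events$animal),
      occasion = events$occasion,
      trap_id = traps$trap_id[events$trap],
      sex = (population$sex %||% rep("unknown", N))[events$animal],
      species = (population$species %||% rep("unknown", N))[events$animal]
    ),
    traps, n_occasions = n_occasions
  )
}

#' Simulate a complete survey data set
#'
#' End-to-end generator: trap layout, habitat mask, chemical fields and
#' composite soil samples, activity centers, and capture histories, all from
#' one [sim_config()] list and one seed. With the default configuration
#' this emulates the full study design the package targets, so the result
#' stands in for the real deposited data set (it is synthetic, not the
#' deposited data).
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed driving every draw.
#' @return List with `traps`, `mask`, `fields` (named list), `samples`
#'   (combined tibble or NULL), `population`, `captures`, `config`, `seed`.
#' @export
simulate_survey <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  traps <- sim_trap_grids(cfg$n_grids, cfg$n_rows, cfg$n_cols,
                          cfg$trap_spacing, cfg$center_spacing,
                          cfg$lateral_offsets, cfg$axis)
  mask <- build_mask(traps, buffer = cfg$buffer, spacing = cfg$mask_spacing)

  fields <- list()
  samples <- NULL
  if (length(cfg$analytes)) {
    grid_pts <- field_raster(traps, cfg$buffer, cfg$field_spacing)
    for (nm in names(cfg$analytes)) {
      fp <- cfg$analytes[[nm]]
      fields[[nm]] <- simulate_field(
        grid_pts, mean = fp$mean, sill = fp$sill, range = fp$range,
        family = fp$family %||% "exponential", trend = fp$trend %||% 0,
        axis = cfg$axis, lognormal = isTRUE(fp$lognormal)
      )
      samples <- dplyr::bind_rows(samples, simulate_soil_samples(
        fields[[nm]], traps, analyte = nm,
        detection_limit = fp$detection_limit %||% 0,
        n_subgrids = cfg$n_subgrids,
        points_per_composite = cfg$points_per_composite,
        noise_sd = cfg$composite_noise
      ))
      if (length(cfg$d_covs) && nm %in% cfg$d_covs) {
        mask <- add_mask_covariate(mask, fields[[nm]], nm)
      }
    }
  }
  population <- simulate_population(
    mask, density = cfg$density, d_covs = cfg$d_covs, d_betas = cfg$d_betas,
    sex_ratio = cfg$sex_ratio, species_probs = cfg$species_probs,
    pi_class = cfg$pi_class
  )
  captures <- simulate_captures(
    population, traps, n_occasions = cfg$n_occasions, g0 = cfg$g0,
    sigma = cfg$sigma, beta_bk = cfg$beta_bk, phi_a = cfg$axis,
    phi_r = cfg$phi_r, mode = cfg$mode
  )
  list(traps = traps, mask = mask, fields = fields, samples = samples,
       population = population, captures = captures, config = cfg,
       seed = seed)
}

# coarse raster covering the buffered trap bounding box
field_raster <- function(traps, buffer, spacing) {
  x0 <- min(traps$x) - buffer; x1 <- max(traps$x) + buffer
  y0 <- min(traps$y) - buffer; y1 <- max(traps$y) + buffer
  xs <- seq(x0 + spacing / 2, x1, by = spacing)
  ys <- seq(y0 + spacing / 2, y1, by = spacing)
  tidyr::expand_grid(y = ys, x = xs)[, c("x", "y")]
}
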