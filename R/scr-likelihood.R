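# Full-likelihood machinery for multi-catch SCR with finite mixtures,
# behavioral response, anisotropic half-normal detection, and log-linear
# inhomogeneous Poisson density. The likelihood is assembled once per data
# set into a closure that precomputes trap-mask geometry and per-individual
# capture contexts. Hazard matrices are cached by the parameters they
# actually depend on, so quasi-Newton finite-difference steps that perturb
# density or mixing parameters do not pay for the mask-by-trap
# exponentials, and behavioral-response hazards are only ever computed for
# the trap columns that appear in some individual's learned set.

make_scr_loglik <- function(captures, traps, mask, spec) {
  traps <- trap_array(traps)
  caps <- tibble::as_tibble(captures)
  T_occ <- n_occasions(captures)
  M <- nrow(mask)
  if (!M) abort("empty habitat mask")

  # geometry: squared displacement components in the anisotropy frame
  dx <- outer(mask$x, traps$x, "-")
  dy <- outer(mask$y, traps$y, "-")
  if (spec$anisotropy) {
    u2 <- (cos(spec$phi_a) * dx + sin(spec$phi_a) * dy)^2
    v2 <- (-sin(spec$phi_a) * dx + cos(spec$phi_a) * dy)^2
  } else {
    d2_iso <- dx^2 + dy^2
  }
  rm(dx, dy)

  # density design matrix (mask covariates on their raw concentration scale)
  miss <- setdiff(spec$d_covs, names(mask))
  if (length(miss)) {
    abort(paste0("mask lacks density covariate(s): ",
                 paste(miss, collapse = ", ")))
  }
  Z <- cbind(`(Intercept)` = rep(1, M))
  for (cv in spec$d_covs) Z <- cbind(Z, mask[[cv]])
  cellarea <- mask_spacing(mask)^2 / 1e4 # hectares

  # per-individual capture context
  ids <- sort(unique(caps$individual_id))
  n_ind <- length(ids)
  caught <- matrix(0L, n_ind, T_occ) # trap index per occasion, 0 = none
  if (nrow(caps)) {
    caught[cbind(match(caps$individual_id, ids), caps$occasion)] <-
      match(caps$trap_id, traps$trap_id)
  }
  # prior[[i]][[t]]: traps where i was caught on an occasion < t
  prior <- lapply(seq_len(n_ind), function(i) {
    out <- vector("list", T_occ)
    seen <- integer(0)
    for (t in seq_len(T_occ)) {
      out[[t]] <- seen
      if (caught[i, t] > 0L) seen <- union(seen, caught[i, t])
    }
    out
  })
  # trap columns that can ever carry a learned (bk) hazard
  bk_traps <- sort(unique(unlist(prior)))
  bk_col <- integer(nrow(traps))
  bk_col[bk_traps] <- seq_along(bk_traps)

  cls <- spec_classes(spec, captures)
  n_cl <- length(cls$levels)
  template <- scr_par_template(spec, captures)
  p_names <- names(template)

  unpack <- function(par) {
    stopifnot(length(par) == length(template))
    par <- setNames(as.numeric(par), p_names)
    g0_off <- sig_off <- rep(0, n_cl)
    if (spec$g0_class && n_cl > 1) {
      g0_off[-1] <- par[paste0("g0.", spec$class_var, cls$levels[-1])]
    }
    if (spec$sigma_class && n_cl > 1) {
      sig_off[-1] <- par[paste0("sigma.", spec$class_var, cls$levels[-1])]
    }
    q <- rep(0, n_cl)
    if (n_cl > 1) q[-1] <- par[paste0("psi.", cls$levels[-1])]
    list(
      d_beta = par[c("D.(Intercept)",
                     if (length(spec$d_covs)) paste0("D.", spec$d_covs))],
      g0_int = par[["g0.(Intercept)"]],
      bk_beta = if (spec$g0_bk) par[["g0.bk"]] else 0,
      g0_off = g0_off,
      sig_int = par[["sigma.(Intercept)"]],
      sig_off = sig_off,
      psi = exp(q) / sum(exp(q)),
      phi_r = if (spec$anisotropy) exp(par[["log(phi_r)"]]) else 1
    )
  }

  cache <- new.env(parent = emptyenv())
  cache$n <- 0L
  key_of <- function(...) paste(format(c(...), digits = 17), collapse = "|")
  cached <- function(key, compute) {
    val <- cache[[key]]
    if (is.null(val)) {
      if (cache$n > 24L) { # flush before the cache outgrows memory
        rm(list = setdiff(ls(cache), "n"), envir = cache)
        cache$n <- 0L
      }
      val <- compute()
      assign(key, val, envir = cache)
      cache$n <- cache$n + 1L
    }
    val
  }
  d2_for <- function(phi_r) {
    if (!spec$anisotropy) return(d2_iso)
    cached(key_of("d2", phi_r), function() u2 + phi_r^2 * v2)
  }
  decay_for <- function(sigma, phi_r) {
    cached(key_of("dec", sigma, phi_r), function() {
      exp(-d2_for(phi_r) / (2 * sigma^2))
    })
  }
  # base hazards for one class: full matrix h, its row sums H
  haz_for <- function(g0, sigma, phi_r) {
    cached(key_of("h", g0, sigma, phi_r), function() {
      h <- -log1p(-g0 * decay_for(sigma, phi_r))
      list(h = h, H = rowSums(h))
    })
  }
  # learned-response hazards, only the bk-relevant trap columns
  hbk_for <- function(g0bk, sigma, phi_r) {
    cached(key_of("hbk", g0bk, sigma, phi_r), function() {
      -log1p(-g0bk * decay_for(sigma, phi_r)[, bk_traps, drop = FALSE])
    })
  }

  loglik <- function(par) {
    th <- unpack(par)
    sigma_c <- exp(th$sig_int + th$sig_off)
    g0_c <- plogis(th$g0_int + th$g0_off)
    g0bk_c <- plogis(th$g0_int + th$g0_off + th$bk_beta)
    if (any(!is.finite(sigma_c)) || any(g0_c >= 1) || any(g0bk_c >= 1) ||
        !is.finite(th$phi_r)) {
      return(-Inf)
    }

    hz <- lapply(seq_len(n_cl), function(c) {
      haz_for(g0_c[c], sigma_c[c], th$phi_r)
    })
    hbk <- if (spec$g0_bk && length(bk_traps)) {
      lapply(seq_len(n_cl), function(c) {
        hbk_for(g0bk_c[c], sigma_c[c], th$phi_r)
      })
    }

    # expected captures: p.(s) marginal over classes (uncaught -> no bk)
    pdot <- numeric(M)
    for (c in seq_len(n_cl)) {
      pdot <- pdot + th$psi[c] * (1 - exp(-T_occ * hz[[c]]$H))
    }
    D_s <- exp(drop(Z %*% th$d_beta))
    Lambda <- sum(D_s * cellarea * pdot)
    if (!is.finite(Lambda)) return(-Inf)

    ll <- -Lambda
    for (i in seq_len(n_ind)) {
      pm <- numeric(M)
      cls_set <- if (is.na(cls$known[i])) seq_len(n_cl) else cls$known[i]
      for (c in cls_set) {
        h <- hz[[c]]$h
        lp <- numeric(M)
        for (t in seq_len(T_occ)) {
          B <- prior[[i]][[t]]
          Hadj <- hz[[c]]$H
          if (spec$g0_bk && length(B)) {
            bc <- bk_col[B]
            if (length(B) == 1L) {
              Hadj <- Hadj - h[, B] + hbk[[c]][, bc]
            } else {
              Hadj <- Hadj - rowSums(h[, B, drop = FALSE]) +
                rowSums(hbk[[c]][, bc, drop = FALSE])
            }
          }
          k <- caught[i, t]
          if (k == 0L) {
            lp <- lp - Hadj
          } else {
            hk <- if (spec$g0_bk && k %in% B) hbk[[c]][, bk_col[k]] else
              h[, k]
            term <- log(hk) - log(Hadj) + log(-expm1(-Hadj))
            term[Hadj == 0] <- -Inf # hazard underflow far from all traps
            lp <- lp + term
          }
        }
        pm <- pm + th$psi[c] * exp(lp)
      }
      lik_i <- sum(D_s * cellarea * pm)
      if (lik_i <= 0 || !is.finite(lik_i)) return(-Inf)
      ll <- ll + log(lik_i)
    }
    ll
  }

  list(loglik = loglik, template = template, unpack = unpack,
       classes = cls, n_ind = n_ind, cellarea = cellarea, Z = Z,
       ids = ids)
}

#' SCR log-likelihood at a given parameter vector
#'
#' Evaluates the full (inhomogeneous-Poisson) multi-catch SCR
#' log-likelihood,
#' `logLik = -Lambda + sum_i log( sum_s D(s) a Pr(omega_i | s) )` with
#' `Lambda = sum_s D(s) a p.(s)`, where the spatial integral over the state
#' space is approximated by the sum over habitat-mask points with cell area
#' `a` (hectares), `Pr(omega_i | s)` is the product over occasions of
#' multinomial cell probabilities (marginalized over mixture classes), and
#' `p.(s)` is the probability an animal centered at `s` is caught at least
#' once. The constant `-log(n!)` term is omitted.
#'
#' @param par Named numeric vector on the link scale; use
#'   [scr_start_values()] for the canonical names and order.
#' @param captures A [capture_data()].
#' @param traps A [trap_array()].
#' @param mask A [build_mask()] habitat mask carrying any density covariates.
#' @param spec An [scr_model_spec()].
#' @return The log-likelihood (scalar; `-Inf` where the parameter vector is
#'   inadmissible).
#' @export
scr_loglik <- function(par, captures, traps, mask, spec) {
  make_scr_loglik(captures, traps, mask, spec)$loglik(par)
}
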