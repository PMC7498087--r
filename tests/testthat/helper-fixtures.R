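# Shared fixture builders; everything generated in code, nothing on disk.

toy_traps <- function(n = 4, spacing = 10) {
  trap_array(tibble::tibble(
    trap_id = paste0("t", seq_len(n)),
    x = (seq_len(n) - 1) * spacing,
    y = 0
  ))
}

toy_captures <- function(traps = toy_traps(), n_occasions = 5) {
  capture_data(
    tibble::tibble(
      individual_id = c("a", "a", "a", "b", "b", "c"),
      occasion = c(1L, 2L, 4L, 1L, 3L, 2L),
      trap_id = c("t1", "t2", "t1", "t3", "t3", "t4"),
      sex = c("M", "M", "M", "F", "F", "unknown"),
      species = "sp1"
    ),
    traps, n_occasions = n_occasions
  )
}

# A capture data set with the reference survey's marginal counts:
# 31 individuals, 78 captures, 47 recaptures (44 spatial), 49 distinct traps
# out of 300, five occasions. Construction: individuals 1-11 caught in five
# distinct traps from a 47-trap pool (4 spatial recaptures each), individual
# 12 caught four times in one trap (3 non-spatial recaptures), individuals
# 13-31 caught once in a shared trap.
survey_marginal_captures <- function() {
  traps <- trap_array(tibble::tibble(
    trap_id = paste0("t", 1:300),
    x = rep(1:20, 15) * 5,
    y = rep(1:15, each = 20) * 5
  ))
  rows <- list()
  pool <- function(j) ((j - 1L) %% 47L) + 1L
  for (i in 1:11) {
    rows[[i]] <- tibble::tibble(
      individual_id = sprintf("m%02d", i),
      occasion = 1:5,
      trap_id = paste0("t", pool((i - 1) * 5 + 1:5))
    )
  }
  rows[[12]] <- tibble::tibble(
    individual_id = "m12", occasion = 1:4, trap_id = "t48"
  )
  rows[[13]] <- tibble::tibble(
    individual_id = sprintf("s%02d", 1:19), occasion = 1L, trap_id = "t49"
  )
  list(
    traps = traps,
    captures = capture_data(dplyr::bind_rows(rows), traps, n_occasions = 5)
  )
}

# Scaled-down three-grid survey geometry used by the simulation-heavy checks
small_geometry <- function() {
  traps <- sim_trap_grids(
    n_grids = 3, n_rows = 5, n_cols = 10, trap_spacing = 4.55,
    center_spacing = 100, lateral_offsets = c(0, 40, 15), axis = 0
  )
  list(traps = traps, mask = build_mask(traps, buffer = 60, spacing = 10))
}

# Enumeration oracle for the toy SCR problem: probability of a full capture
# history (one individual, arbitrary traps/occasions) given an activity
# center, with optional bk response -- written directly from the multinomial
# cells, independent of the package's likelihood code.
oracle_history_prob <- function(sx, sy, trap_xy, history, g0, sigma,
                                beta_bk = 0, phi_a = 0, phi_r = 1) {
  n_traps <- nrow(trap_xy)
  seen <- rep(FALSE, n_traps)
  pr <- 1
  for (t in seq_along(history)) {
    dxy <- cbind(trap_xy[, 1] - sx, trap_xy[, 2] - sy)
    d <- aniso_transform(dxy[, 1], dxy[, 2], phi_a, phi_r)
    g0v <- plogis(qlogis(g0) + beta_bk * seen)
    g <- g0v * exp(-d^2 / (2 * sigma^2))
    h <- -log(1 - g)
    H <- sum(h)
    cells <- if (H == 0) c(1, rep(0, n_traps)) else
      c(exp(-H), (h / H) * (1 - exp(-H)))
    pr <- pr * cells[history[t] + 1]
    if (history[t] > 0) seen[history[t]] <- TRUE
  }
  pr
}

# Oracle full log-likelihood on a toy problem (homogeneous density)
oracle_loglik <- function(D, g0, sigma, beta_bk, captures, traps, mask,
                          phi_a = 0, phi_r = 1) {
  trap_xy <- as.matrix(traps[, c("x", "y")])
  a <- mask_spacing(mask)^2 / 1e4
  T_occ <- n_occasions(captures)
  caps <- tibble::as_tibble(captures)
  ids <- sort(unique(caps$individual_id))
  hist_of <- function(id) {
    h <- integer(T_occ)
    rows <- caps[caps$individual_id == id, ]
    h[rows$occasion] <- match(rows$trap_id, traps$trap_id)
    h
  }
  pdot <- vapply(seq_len(nrow(mask)), function(s) {
    1 - oracle_history_prob(mask$x[s], mask$y[s], trap_xy,
                            integer(T_occ), g0, sigma, beta_bk,
                            phi_a, phi_r)
  }, 0)
  ll <- -sum(D * a * pdot)
  for (id in ids) {
    h <- hist_of(id)
    pr <- vapply(seq_len(nrow(mask)), function(s) {
      oracle_history_prob(mask$x[s], mask$y[s], trap_xy, h, g0, sigma,
                          beta_bk, phi_a, phi_r)
    }, 0)
    ll <- ll + log(sum(D * a * pr))
  }
  ll
}
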