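#' Gehan-Wilcoxon test for left-censored data
#'
#' Generalized Wilcoxon two-sample test that accommodates nondetects
#' (left-censored observations reported at their detection limits). Each
#' cross-group pair (i in A, j in B) is scored
#' `+1` when i is unambiguously greater than j, `-1` when unambiguously
#' less, and `0` when censoring makes the ordering indeterminate:
#' a nondetect at DL is only unambiguously *less* than an uncensored value
#' strictly above DL, and two nondetects are never ordered. The statistic is
#' `W = sum of scores`; the two-sided p-value comes from the permutation
#' distribution of group labels -- complete enumeration when the pooled
#' sample size is at most 10, otherwise `n_perm` Monte-Carlo draws.
#'
#' @param group_a,group_b Either numeric vectors (all uncensored) or data
#'   frames with columns `concentration` and `censored`.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @return A `group_test` object; see [tidy.group_test()].
#' @examples
#' gehan_wilcoxon(c(4, 5, 6), c(1, 2, 3))$p_value # 2/20
#' @export
gehan_wilcoxon <- function(group_a, group_b, n_perm = 2000, seed = NULL) {
  a <- as_censored_obs(group_a)
  b <- as_censored_obs(group_b)
  if (!nrow(a) || !nrow(b)) abort("both groups must be nonempty")
  obs <- rbind(a, b)
  n <- nrow(obs)
  na <- nrow(a)
  if (all(obs$censored) && length(unique(obs$value)) == 1L) {
    warn("all observations censored at the same detection limit: no information")
    return(new_group_test(0, 1, "Gehan-Wilcoxon permutation test",
                          exact = TRUE))
  }
  h <- gehan_scores(obs$value, obs$censored)
  w_for <- function(ia) sum(h[ia, -ia, drop = FALSE])
  w_obs <- w_for(seq_len(na))

  if (n <= 10L) {
    combos <- combn(n, na)
    ws <- apply(combos, 2L, w_for)
    p <- mean(abs(ws) >= abs(w_obs) - 1e-12)
    exact <- TRUE
  } else {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_seed(old), add = TRUE)
      set.seed(seed)
    }
    ws <- vapply(seq_len(n_perm), function(i) w_for(sample.int(n, na)), 0)
    p <- (1 + sum(abs(ws) >= abs(w_obs) - 1e-12)) / (n_perm + 1)
    exact <- FALSE
  }
  new_group_test(w_obs, p, "Gehan-Wilcoxon permutation test", exact = exact)
}

# pairwise Gehan scores h[i, j] = +1 if obs i unambiguously > obs j
gehan_scores <- function(value, censored) {
  n <- length(value)
  vi <- matrix(value, n, n)
  vj <- t(vi)
  ci <- matrix(censored, n, n)
  cj <- t(ci)
  h <- matrix(0L, n, n)
  h[!ci & !cj & vi > vj] <- 1L
  h[!ci & !cj & vi < vj] <- -1L
  h[!ci & cj & vi > vj] <- 1L   # detect above j's DL beats nondetect
  h[ci & !cj & vj > vi] <- -1L  # nondetect below an exceeding detect
  h
}

as_censored_obs <- function(g) {
  if (is.numeric(g)) {
    return(tibble::tibble(value = as.numeric(g),
                          censored = rep(FALSE, length(g))))
  }
  g <- tibble::as_tibble(g)
  if (!all(c("concentration", "censored") %in% names(g))) {
    abort("groups must be numeric vectors or have columns 'concentration' and 'censored'")
  }
  tibble::tibble(value = g$concentration, censored = as.logical(g$censored))
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

new_group_test <- function(statistic, p_value, method, exact = NA,
                           pairwise = NULL) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         exact = exact, pairwise = pairwise),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 4),
      " p =", format.pval(x$p_value, digits = 3), "\n")
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Bonferroni-adjusted):\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Tidy a group-comparison test
#'
#' @param x A `group_test` from [gehan_wilcoxon()] or [kruskal_dunn()].
#' @param ... Unused.
#' @return One-row tibble (`statistic`, `p_value`, `method`) with the
#'   pairwise table, when present, as a nested list column.
#' @export
tidy.group_test <- function(x, ...) {
  out <- tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                        method = x$method)
  if (!is.null(x$pairwise)) out$pairwise <- list(x$pairwise)
  out
}

#' Kruskal-Wallis test with Dunn-Bonferroni post hoc comparisons
#'
#' Omnibus Kruskal-Wallis one-way ANOVA on ranks (tie-corrected H, chi-square
#' p-value via [stats::kruskal.test()]); when the omnibus p-value is below
#' `alpha`, Dunn's z tests compare each pair of groups on the pooled mean
#' ranks with the tie-corrected variance, and pairwise p-values are
#' Bonferroni-adjusted (multiplied by the number of pairs, capped at 1).
#' Intended for uncensored analytes; censored analytes route to
#' [gehan_wilcoxon()].
#'
#' @param data Either a data frame with columns `value` and `group`, or a
#'   (optionally named) list of numeric vectors.
#' @param alpha Omnibus significance level gating the post hoc tests.
#' @return A `group_test` with a `pairwise` tibble
#'   (`group_1`, `group_2`, `z`, `p_raw`, `p_adj`) when the omnibus test is
#'   significant.
#' @export
kruskal_dunn <- function(data, alpha = 0.05) {
  if (is.data.frame(data)) {
    if (!all(c("value", "group") %in% names(data))) {
      abort("data frame input needs columns 'value' and 'group'")
    }
    groups <- split(as.numeric(data$value), as.character(data$group))
  } else {
    groups <- data
    if (is.null(names(groups))) {
      names(groups) <- paste0("group_", seq_along(groups))
    }
  }
  if (length(groups) < 2L) abort("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    abort(paste0("empty group(s): ",
                 paste(names(groups)[sizes == 0L], collapse = ", ")))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), sizes)
  if (length(unique(values)) == 1L) {
    # all observations tied: no evidence of any difference
    return(new_group_test(0, 1, "Kruskal-Wallis rank sum test"))
  }
  kw <- kruskal.test(values, factor(labels))
  pairwise <- NULL
  if (kw$p.value < alpha) {
    N <- length(values)
    r <- rank(values)
    rbar <- tapply(r, labels, mean)
    ties <- table(values)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    v0 <- N * (N + 1) / 12 - tie_term
    combos <- combn(names(groups), 2L)
    n_pairs <- ncol(combos)
    pairwise <- purrr::map_dfr(seq_len(n_pairs), function(j) {
      g1 <- combos[1, j]; g2 <- combos[2, j]
      se <- sqrt(v0 * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
      z <- (rbar[[g1]] - rbar[[g2]]) / se
      p_raw <- 2 * pnorm(-abs(z))
      tibble::tibble(group_1 = g1, group_2 = g2, z = z, p_raw = p_raw,
                     p_adj = min(1, p_raw * n_pairs))
    })
  }
  new_group_test(unname(kw$statistic), kw$p.value,
                 "Kruskal-Wallis rank sum test", pairwise = pairwise)
}

#' Screen analytes for among-grid concentration differences
#'
#' Chemicals only enter the kriging/density stages when their concentrations
#' differ among trapping grids (otherwise there is no spatial signal worth
#' interpolating). For each analyte: if any record is censored, all grid
#' pairs are compared with [gehan_wilcoxon()] and Bonferroni-adjusted over
#' pairs (the analyte's screening p is the smallest adjusted pairwise p);
#' with no censoring the omnibus [kruskal_dunn()] p is used. Analytes with
#' screening p below `alpha` are retained.
#'
#' @param samples Soil-sample records ([chem_samples()]), several analytes.
#' @param alpha Screening significance level.
#' @param n_perm,seed Passed to [gehan_wilcoxon()].
#' @return Tibble with one row per analyte: `analyte`, `method`, `p_value`,
#'   `retained`, and nested `detail` (pairwise tables).
#' @export
screen_chemicals <- function(samples, alpha = 0.05, n_perm = 2000,
                             seed = NULL) {
  samples <- chem_samples(samples)
  out <- purrr::map_dfr(split(samples, samples$analyte), function(d) {
    grids <- unique(d$grid)
    if (length(grids) < 2L) {
      abort(paste0("analyte '", d$analyte[1],
                   "' was sampled on a single grid; nothing to compare"))
    }
    if (any(d$censored)) {
      combos <- combn(grids, 2L)
      n_pairs <- ncol(combos)
      pw <- purrr::map_dfr(seq_len(n_pairs), function(j) {
        ga <- d[d$grid == combos[1, j], ]
        gb <- d[d$grid == combos[2, j], ]
        tt <- gehan_wilcoxon(ga, gb, n_perm = n_perm, seed = seed)
        tibble::tibble(group_1 = combos[1, j], group_2 = combos[2, j],
                       statistic = tt$statistic, p_raw = tt$p_value,
                       p_adj = min(1, tt$p_value * n_pairs))
      })
      tibble::tibble(analyte = d$analyte[1],
                     method = "pairwise Gehan-Wilcoxon (Bonferroni)",
                     p_value = min(pw$p_adj), detail = list(pw))
    } else {
      tt <- kruskal_dunn(tibble::tibble(value = d$concentration,
                                        group = d$grid), alpha = alpha)
      tibble::tibble(analyte = d$analyte[1], method = tt$method,
                     p_value = tt$p_value,
                     detail = list(tt$pairwise %||% tibble::tibble()))
    }
  })
  out$retained <- out$p_value < alpha
  dplyr::relocate(out, "retained", .after = "p_value")
}
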