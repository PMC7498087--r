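test_that("fully separated groups give the exact enumeration p-value", {
  g <- gehan_wilcoxon(c(4, 5, 6), c(1, 2, 3))
  expect_equal(g$statistic, 9)
  expect_equal(g$p_value, 2 / 20) # 2 extreme assignments of C(6,3)
  expect_true(g$exact)
})

test_that("with no censoring the Gehan test is permutation-equivalent to the rank-sum test", {
  set.seed(101)
  for (rep in 1:8) {
    a <- rnorm(sample(3:5, 1)) # untied: exact rank-sum p is well-defined
    b <- rnorm(sample(3:5, 1), mean = runif(1, -1, 1))
    g <- gehan_wilcoxon(a, b)
    w <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    expect_equal(g$p_value, w$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate and symmetric censored inputs behave", {
  ident <- gehan_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  cens <- tibble::tibble(concentration = rep(0.5, 3),
                         censored = TRUE)
  expect_warning(res <- gehan_wilcoxon(cens, cens), "no information")
  expect_equal(res$p_value, 1)
})

test_that("censored comparisons only count unambiguous orderings", {
  # nondetect at 10 vs detect at 12: detect unambiguously greater;
  # nondetect at 10 vs detect at 8: indeterminate
  a <- tibble::tibble(concentration = c(12, 8), censored = FALSE)
  b <- tibble::tibble(concentration = c(10, 10), censored = TRUE)
  h <- scrsoil:::gehan_scores(c(a$concentration, b$concentration),
                              c(a$censored, b$censored))
  expect_identical(h[1, 3], 1L)  # 12 > ND(10)
  expect_identical(h[2, 3], 0L)  # 8 vs ND(10) indeterminate
  expect_identical(h[3, 4], 0L)  # two nondetects never ordered
  expect_identical(h[3, 1], -1L) # symmetry
})

test_that("Kruskal-Wallis H matches hand rank arithmetic and Dunn z follows", {
  # groups {1,2,3},{4,5,6},{7,8,9}: mean ranks 2, 5, 8;
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 = 12/90 * 3*18 = 7.2
  kd <- kruskal_dunn(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kd$statistic, 7.2)
  expect_equal(kd$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  # Dunn z for (a, c): (2 - 8) / sqrt((9*10/12) * (2/3))
  z_ac <- -6 / sqrt(7.5 * 2 / 3)
  pw <- kd$pairwise
  expect_equal(pw$z[pw$group_1 == "a" & pw$group_2 == "c"], z_ac)
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 3))
  expect_true(all(pw$p_adj >= pw$p_raw))
})

test_that("identical groups give H = 0, p = 1, and no post hoc tests", {
  kd <- kruskal_dunn(list(rep(2, 4), rep(2, 4), rep(2, 4)))
  expect_equal(kd$statistic, 0)
  expect_equal(kd$p_value, 1)
  expect_null(kd$pairwise)
  expect_error(kruskal_dunn(list(1:3, numeric(0))), "empty group")
  expect_error(kruskal_dunn(list(1:3)), "at least two groups")
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum test asymptotically", {
  set.seed(7)
  a <- rnorm(30)
  b <- rnorm(30, 0.6)
  kw <- kruskal_dunn(list(a, b))
  wt <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(kw$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("screening retains analytes with real among-grid differences", {
  set.seed(11)
  mk_samples <- function(analyte, means, censor_dl = 0) {
    purrr::map_dfr(1:3, function(g) {
      conc <- pmax(rnorm(6, means[g], 1), 0.01)
      cens <- conc <= censor_dl
      tibble::tibble(
        sample_id = paste0(analyte, g, 1:6), grid = paste0("grid", g),
        x = g * 100 + 1:6, y = 1:6, analyte = analyte,
        concentration = ifelse(cens, censor_dl, conc),
        detection_limit = ifelse(censor_dl > 0, censor_dl, NA),
        censored = cens
      )
    })
  }
  strong <- mk_samples("hot", c(20, 10, 10))      # 10 SD separation
  null_a <- mk_samples("flat", c(10, 10, 10))
  cens_s <- mk_samples("cens", c(4, 1, 1), censor_dl = 1.2)
  out <- screen_chemicals(dplyr::bind_rows(strong, null_a, cens_s),
                          seed = 5)
  expect_true(out$retained[out$analyte == "hot"])
  expect_true(out$retained[out$analyte == "cens"])
  expect_match(out$method[out$analyte == "cens"], "Gehan")
  expect_match(out$method[out$analyte == "hot"], "Kruskal")
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))

  single <- strong[strong$grid == "grid1", ]
  expect_error(screen_chemicals(single), "single grid")
})

test_that("screening holds its type-I error rate on null data", {
  set.seed(202)
  n_rep <- 400
  hits <- 0L
  for (r in seq_len(n_rep)) {
    s <- purrr::map_dfr(1:3, function(g) {
      tibble::tibble(
        sample_id = paste0(g, 1:6), grid = paste0("g", g),
        x = g * 100 + 1:6, y = 1:6, analyte = "x",
        concentration = rlnorm(6), detection_limit = NA, censored = FALSE
      )
    })
    hits <- hits + screen_chemicals(s)$retained[1]
  }
  rate <- hits / n_rep
  # binomial 99% band around alpha = 0.05 at 400 replicates
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_rep))
})
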