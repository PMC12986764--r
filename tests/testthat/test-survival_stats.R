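# Hand-rank oracles computed inline; expected values frozen from them.

test_that("Spearman correlation matches the hand-rank oracle", {
  rows <- function(p, o) data.frame(criterion = "RANO", pfs_months = p, os_months = o)
  expect_equal(spearman_pfs_os(rows(1:10, (1:10)^2))$rho, 1)
  expect_equal(spearman_pfs_os(rows(1:10, 10:1))$rho, -1)
  # 5-point set {(1,2),(2,1),(3,4),(4,3),(5,5)}: d^2 = (1,1,1,1,0),
  # rho = 1 - 6*4/(5*24) = 0.8
  r <- spearman_pfs_os(rows(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)))
  expect_equal(r$rho, 0.8)
  expect_identical(r$n, 5L)
  # t-approximation p-value: t = rho*sqrt((n-2)/(1-rho^2))
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-12)
  expect_error(spearman_pfs_os(rows(rep(2, 5), 1:5)),
               class = "ranovol_undefined_correlation")
  expect_error(spearman_pfs_os(rows(1:2, 2:1)), class = "ranovol_domain_error")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rlnorm(20); y <- rlnorm(20) * x
  f <- function(v) log(v + 1)^3
  r1 <- spearman_pfs_os(data.frame(pfs_months = x, os_months = y))
  r2 <- spearman_pfs_os(data.frame(pfs_months = f(x), os_months = f(y)))
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  g <- list(rlnorm(8), rlnorm(8) + 1, rlnorm(8))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, f))$statistic, tolerance = 1e-12)
  expect_equal(mann_whitney(g[[1]], g[[2]])$U,
               mann_whitney(f(g[[1]]), f(g[[2]]))$U, tolerance = 1e-12)
  expect_equal(dunn_bonferroni(g)$z, dunn_bonferroni(lapply(g, f))$z,
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches the hand-rank oracle and handles ties", {
  g <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  # ranks 1..9, mean ranks 2/5/8: H = 12/(9*10) * 3*(4+25+64) - 3*10 = 7.2
  expect_equal(kruskal_wallis(g)$statistic, 7.2, tolerance = 1e-12)
  expect_identical(kruskal_wallis(g)$df, 2L)
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(same)$statistic, 0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(same)$p_value, 1, tolerance = 1e-12)
  tied <- list(c(5, 5, 5), c(5, 5), c(5, 5, 5))
  expect_equal(kruskal_wallis(tied)$statistic, 0)
  expect_equal(kruskal_wallis(tied)$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), class = "ranovol_domain_error")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), class = "ranovol_domain_error")
})

test_that("Dunn z statistics match a brute-force rank recomputation", {
  g <- list(a = c(1, 2, 3), b = c(10, 11, 12), c = c(20, 21, 22))
  d <- dunn_bonferroni(g)
  # brute force: pooled ranks, no ties
  r <- rank(unlist(g))
  mr <- tapply(r, rep(1:3, each = 3), mean)
  sigma2 <- 9 * 10 / 12
  z_oracle <- function(i, j) (mr[i] - mr[j]) / sqrt(sigma2 * (2 / 3))
  expect_equal(d$z, c(z_oracle(1, 2), z_oracle(1, 3), z_oracle(2, 3)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(d$p_adj, pmin(1, d$p_raw * 3), tolerance = 1e-15)
  expect_true(all(d$p_adj >= d$p_raw))

  ident <- dunn_bonferroni(list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)))
  expect_equal(ident$p_adj, rep(1, 3))

  two <- dunn_bonferroni(list(c(1, 2), c(3, 4)))
  expect_identical(nrow(two), 1L)
  expect_equal(two$p_adj, two$p_raw)  # single pair: adjustment factor 1
})

test_that("Mann-Whitney U matches pair enumeration", {
  # {1,2,3} vs {4,5,6}: every one of the 9 pairs favors b, so U = 0
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0, ignore_attr = TRUE)
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 0.9)
  expect_true(mann_whitney(1, 2)$U %in% c(0, 1))
  expect_error(mann_whitney(numeric(0), 1), class = "ranovol_domain_error")
})

test_that("Cox beta matches a partial-likelihood grid oracle to 1e-3", {
  # interleaved event times: finite maximum of the partial likelihood
  time <- c(2, 4, 9, 3, 8, 10)
  event <- rep(TRUE, 6)
  flag <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_binary(time, event, flag)
  oracle <- optimize(function(b) -cox_logpl(b, time, event, flag), c(-8, 8))$minimum
  expect_equal(fit$beta, oracle, tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$beta), tolerance = 1e-12)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  expect_false(fit$monotone)

  # fully separated groups (every exposed death precedes every control death):
  # the likelihood is monotone in beta and the fit must say so
  sep <- cox_binary(c(2, 3, 4, 8, 9, 10), rep(TRUE, 6), c(1, 1, 1, 0, 0, 0))
  expect_true(sep$monotone)
})

test_that("Cox invariances: duplication and group-relabelling antisymmetry", {
  set.seed(8)
  time <- rexp(30) + 0.1
  event <- runif(30) < 0.8
  flag <- rep(c(1, 0), 15)
  fit <- cox_binary(time, event, flag, ties = "breslow")
  dup <- cox_binary(rep(time, 2), rep(event, 2), rep(flag, 2), ties = "breslow")
  expect_equal(fit$beta, dup$beta, tolerance = 1e-6)
  swap <- cox_binary(time, event, 1 - flag, ties = "breslow")
  expect_equal(swap$hr, 1 / fit$hr, tolerance = 1e-6)
  # Efron is the default and differs from Breslow only in tied data
  expect_equal(cox_binary(time, event, flag)$beta, fit$beta, tolerance = 1e-8)
})

test_that("degenerate Cox inputs are flagged or rejected", {
  expect_error(cox_binary(1:4, c(TRUE, TRUE, FALSE, TRUE), c(1, 1, 1, 1)),
               class = "ranovol_degenerate_stratification")
  expect_error(cox_binary(1:4, rep(FALSE, 4), c(1, 0, 1, 0)),
               class = "ranovol_domain_error")
  # single event in one of two single-patient groups: monotone likelihood
  res <- cox_binary(c(1, 2), c(TRUE, FALSE), c(1, 0))
  expect_true(res$monotone)
})

test_that("landmark analysis stratifies residual survival by progression status", {
  rows <- data.frame(
    criterion = "RANO",
    patient_id = sprintf("p%d", 1:8),
    pfs_months = c(4, 5, 6, 9, 10, 11, 3, 2),
    pfs_event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    os_months = c(10, 12, 17, 11, 16, 18, 7, 6),
    os_event = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  lm <- landmark_analysis(rows, 8)
  # p7 and p8 died at or before the landmark and are excluded
  expect_identical(lm$n_included, 6L)
  expect_identical(lm$n_pd, 3L)
  expect_identical(lm$n_sd, 3L)
  expect_identical(lm$n_sd + lm$n_pd, lm$n_included)
  expect_equal(lm$median_os_pd, 4)   # residuals 2, 4, 9
  expect_equal(lm$median_os_sd, 8)   # residuals 3, 8, 10
  oracle <- optimize(function(b) -cox_logpl(b, c(2, 4, 9, 3, 8, 10), rep(TRUE, 6),
                                            c(1, 1, 1, 0, 0, 0)), c(-8, 8))$minimum
  expect_equal(log(lm$hr), oracle, tolerance = 1e-3)
  expect_true(lm$ci_low <= lm$hr && lm$hr <= lm$ci_high)

  # every included patient progression-free at the landmark: degenerate
  rows_sd <- rows
  rows_sd$pfs_event <- FALSE
  expect_error(landmark_analysis(rows_sd, 8),
               class = "ranovol_degenerate_stratification")
  expect_error(landmark_analysis(rows, 0), class = "ranovol_domain_error")
})
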