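test_that("Kendall tau matches brute-force concordance counting", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  got <- kendall_tau(x, y)
  orc <- oracle_kendall(x, y, exact_p = TRUE)
  expect_equal(got$value, orc$tau)
  expect_equal(got$p_value, orc$p_two_sided)

  expect_equal(kendall_tau(1:8, 1:8)$value, 1)
  expect_equal(kendall_tau(1:8, 8:1)$value, -1)
  expect_error(kendall_tau(1:5, rep(2, 5)), "constant")

  set.seed(501)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    got <- kendall_tau(x, y)
    orc <- oracle_kendall(x, y, exact_p = TRUE)
    expect_equal(got$value, orc$tau)
    expect_equal(got$p_value, orc$p_two_sided)
    # base R cross-check of the estimate
    expect_equal(got$value, unname(cor.test(x, y, method = "kendall")$estimate))
  }
})

test_that("tau-b tie correction agrees with base R on tied data", {
  set.seed(502)
  x <- sample(1:4, 40, replace = TRUE)
  y <- x + sample(0:2, 40, replace = TRUE)
  got <- kendall_tau(x, y)
  expect_equal(got$value, unname(cor.test(x, y, method = "kendall",
                                          exact = FALSE)$estimate))
  expect_equal(got$p_value,
               cor.test(x, y, method = "kendall", exact = FALSE,
                        continuity = FALSE)$p.value, tolerance = 1e-8)
})

test_that("rank-sum test agrees with enumeration and base R", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  orc <- oracle_ranksum_exact(a, b)
  expect_equal(orc$W, 6)                        # minimal possible rank sum
  got <- wilcoxon_rank_sum(a, b)
  expect_lt(got$value, 0)                       # a smaller than b
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)

  set.seed(503)
  x <- rnorm(12); y <- rnorm(15) + 0.3
  got <- wilcoxon_rank_sum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)

  # ties: midranks and tie-corrected variance
  x <- c(1, 1, 2, 3, 3, 3); y <- c(2, 2, 3, 4, 4)
  got <- wilcoxon_rank_sum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)

  # near-identical equal samples: Z near 0, p near 1
  got <- wilcoxon_rank_sum(1:10, 1:10 + 0.001)
  expect_lt(abs(got$value), 0.5)
  expect_gt(got$p_value, 0.5)
})

test_that("rank-sum power increases with the shift alternative", {
  set.seed(504)
  pow <- vapply(c(0, 0.5, 1.2), function(shift) {
    mean(replicate(200, {
      wilcoxon_rank_sum(rnorm(15), rnorm(15) + shift)$p_value < 0.05
    }))
  }, 0)
  expect_true(all(diff(pow) > 0))
})

test_that("signed-rank test matches exhaustive sign-flip enumeration", {
  d <- c(1.2, -0.5, 2.1, -3.3, 0.7, 1.9)
  got <- wilcoxon_signed_rank(d)
  orc <- oracle_signedrank_exact(d)
  expect_equal(got$p_value, orc$p_two_sided)

  # with tied absolute values the enumeration path is used (n <= 12)
  d2 <- c(1, -1, 2, 2, -3, 4, 1)
  got2 <- wilcoxon_signed_rank(d2)
  orc2 <- oracle_signedrank_exact(d2)
  expect_equal(got2$p_value, orc2$p_two_sided)

  # untied, n <= 25: equals base R exact test
  set.seed(505)
  d3 <- rnorm(18)
  got3 <- wilcoxon_signed_rank(d3)
  ref <- wilcox.test(d3, exact = TRUE)
  expect_equal(got3$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("signed-rank T carries the direction of the dominant rank sum", {
  d <- c(-1, -2, -3, -4, 5)          # negatives dominate
  got <- wilcoxon_signed_rank(d)
  expect_lt(got$value, 0)
  # W+ = 5 (rank of |5|), W- = 10, T = (5 - 10)/2
  expect_equal(got$value, -2.5)
  # antisymmetric set: T = 0, p large
  d0 <- c(1, -1, 2, -2, 3, -3)
  got0 <- wilcoxon_signed_rank(d0)
  expect_equal(got0$value, 0)
  expect_gt(got0$p_value, 0.9)
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "degenerate")
})

test_that("signed-rank p decreases with a negative location effect", {
  set.seed(506)
  p <- vapply(c(0, -0.4, -1), function(mu) {
    median(replicate(60, wilcoxon_signed_rank(rnorm(30, mu))$p_value))
  }, 0)
  expect_true(all(diff(p) < 0))
})

test_that("Kruskal-Wallis H matches the rank formula and base R", {
  got <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  # R = (3, 7, 11); H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7
  expect_equal(got$value, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21)
  ref <- kruskal.test(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(got$value, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)

  set.seed(507)
  g <- list(rnorm(10), rnorm(12) + 0.5, sample(1:5, 8, TRUE))
  got <- kruskal_wallis(g)
  ref <- kruskal.test(g)
  expect_equal(got$value, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")

  # permuting group labels leaves H invariant
  expect_equal(kruskal_wallis(g[c(3, 1, 2)])$value, got$value)
})

test_that("Williams-corrected G-test matches the formula oracle", {
  expect_equal(g_test_williams(rbind(c(10, 20, 30), c(20, 40, 60)))$value, 0)
  tab <- rbind(c(5, 10, 15), c(15, 10, 5))
  got <- g_test_williams(tab)
  expect_equal(got$value, oracle_g_williams(tab))
  expect_equal(got$df, 2)
  expect_error(g_test_williams(rbind(c(0, 0, 0), c(1, 2, 3))),
               "zero marginal")
})

test_that("stepwise regression selects an exact predictor with R-square one", {
  set.seed(508)
  X <- data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  y <- 2 * X$x2
  m <- suppressWarnings(stepwise_regression(y, X))  # perfect fit by design
  expect_identical(m$selected_terms, "x2")
  expect_equal(m$r_square, 1, tolerance = 1e-9)
  expect_equal(m$coefficients$estimate[m$coefficients$term == "x2"], 2,
               tolerance = 1e-9)
})

test_that("stepwise selection path matches an independent algebraic oracle", {
  set.seed(509)
  for (rep in 1:8) {
    n <- 10
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    y <- 0.8 * X$x1 - 0.5 * X$x3 + rnorm(n, sd = 0.7)
    m <- stepwise_regression(y, X)
    orc <- oracle_stepwise(y, X)
    expect_identical(m$selected_terms, orc$included)
    if (length(orc$included)) {
      est <- setNames(m$coefficients$estimate,
                      sub("Intercept", "(Intercept)", m$coefficients$term))
      expect_equal(est[names(orc$coefficients)], orc$coefficients,
                   tolerance = 1e-8)
    }
  }
})

test_that("the final fit satisfies the normal equations and the ANOVA identity", {
  set.seed(510)
  n <- 60
  X <- data.frame(struct = sample(c("homogeneous", "heterogeneous"), n, TRUE),
                  loc = sample(c("same", "different"), n, TRUE),
                  span = runif(n, 100, 5000), ks = runif(n, 0, 0.14))
  y <- 0.01 * (X$loc == "different") + 0.1 * X$ks + rnorm(n, sd = 0.005)
  m <- stepwise_regression(y, X)
  a <- m$anova
  expect_equal(a$model_ss + a$error_ss, a$total_ss, tolerance = 1e-10)
  expect_equal(a$model_df, length(m$selected_terms))
  # residuals orthogonal to the selected design columns
  res <- residuals(m$fit)
  mm <- model.matrix(m$fit)
  expect_lt(max(abs(crossprod(mm, res))) / sum(res^2), 1e-8)
  # nominal coding: reference levels recorded
  expect_identical(m$references$loc, "same")
  expect_identical(m$references$struct, "homogeneous")
})

test_that("collinear candidates are never co-selected", {
  set.seed(511)
  n <- 30
  x1 <- rnorm(n)
  X <- data.frame(x1 = x1, x2 = 2 * x1, x3 = rnorm(n))
  y <- x1 + rnorm(n, sd = 0.1)
  m <- stepwise_regression(y, X)
  expect_false(all(c("x1", "x2") %in% m$selected_terms))
})

test_that("cohort significance profile tabulates fractions with counts", {
  ks <- c(0.005, 0.02, 0.02, 0.04, 0.06, 0.1, 0.1, 0.1)
  sig <- c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  prof <- cohort_significance_profile(assign_cohort(ks), sig)
  expect_equal(nrow(prof), 5L)
  expect_equal(prof$n, c(1L, 2L, 1L, 1L, 3L))
  expect_equal(prof$frac_nt, c(0, 0.5, 1, 1, 2 / 3))
  # all-nonsignificant input gives all-zero fractions
  prof0 <- cohort_significance_profile(assign_cohort(ks), rep(FALSE, 8))
  expect_true(all(prof0$frac_nt == 0))
  # an empty cohort reports NA
  prof1 <- cohort_significance_profile(assign_cohort(c(0.005, 0.1)),
                                       c(TRUE, FALSE))
  expect_true(is.na(prof1$frac_nt[2]))
})
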