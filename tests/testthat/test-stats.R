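test_that("pooled two-sample t matches the closed-form oracle", {
  # identical groups: null identity
  r0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # hand-solved pooled-variance computation: means 2 and 5, each s^2 = 1,
  # pooled s^2 = 1, se = sqrt(2/3), t = -3 / sqrt(2/3)
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)

  # group sizes 24 and 32 report on 54 degrees of freedom
  set.seed(1)
  r54 <- two_sample_t(rnorm(24), rnorm(32))
  expect_equal(r54$df, 54)
})

test_that("one-sample t against a reference value", {
  expect_equal(one_sample_t_vs(rep(1, 5), 1)$statistic, 0)
  set.seed(2)
  x <- rnorm(26, mean = 1.2, sd = 0.4)
  r <- one_sample_t_vs(x, 1)
  expect_equal(r$df, 25)
  # direct formula oracle
  expect_equal(r$statistic, (mean(x) - 1) / (sd(x) / sqrt(26)),
               tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(r$statistic), 25), tolerance = 1e-12)
})

test_that("bootstrapped Pearson correlation is seeded and calibrated", {
  x <- 1:20
  r1 <- pearson_r_bootstrap(x, x + 0, n_boot = 200, seed = 3)
  expect_equal(r1$estimate, 1)

  set.seed(4)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(pearson_r_bootstrap(a, b, n_boot = 50, seed = 1)$estimate), 0.1)

  set.seed(5)
  u <- rnorm(32); v <- 0.5 * u + rnorm(32)
  r32 <- pearson_r_bootstrap(u, v, n_boot = 500, seed = 9)
  expect_equal(r32$df, 30) # r(30) reporting convention at n = 32
  r32b <- pearson_r_bootstrap(u, v, n_boot = 500, seed = 9)
  expect_identical(r32$ci, r32b$ci)
  # CI brackets the point estimate and p agrees with cor.test
  expect_true(r32$ci[1] < r32$estimate && r32$estimate < r32$ci[2])
  expect_equal(r32$p_value, cor.test(u, v)$p.value)
})

test_that("Steiger Z1* behaves as a dependent-correlation test", {
  expect_equal(compare_dependent_correlations(0.5, 0.5, 0.3, 40)$statistic, 0)
  zp <- compare_dependent_correlations(0.6, 0.2, 0.3, 50)
  zn <- compare_dependent_correlations(0.2, 0.6, 0.3, 50)
  expect_equal(zp$statistic, -zn$statistic, tolerance = 1e-12)

  # resampling oracle: the z denominator approximates the Monte-Carlo
  # standard deviation of z1 - z2 at the population correlations
  set.seed(6)
  R <- matrix(c(1, 0.6, 0.2,
                0.6, 1, 0.3,
                0.2, 0.3, 1), 3, 3)
  cr <- chol(R)
  n <- 50
  diffs <- replicate(4000, {
    d <- matrix(rnorm(n * 3), n, 3) %*% cr
    atanh(cor(d[, 1], d[, 2])) - atanh(cor(d[, 1], d[, 3]))
  })
  z_mc <- (atanh(0.6) - atanh(0.2)) / sd(diffs)
  expect_equal(zp$statistic, z_mc, tolerance = 0.12 * abs(z_mc))

  expect_error(compare_dependent_correlations(1, 0.2, 0.3, 50), "in \\(-1, 1\\)")
  expect_error(compare_dependent_correlations(0.9, -0.9, 0.9, 50),
               "positive semidefinite")
})

test_that("Type III ANCOVA matches the nested-model RSS oracle", {
  set.seed(7)
  n <- 8
  fixed <- rep(c("a", "b"), each = 4)
  covariate <- rnorm(n)
  y <- 0.8 * (fixed == "b") + 0.5 * covariate + rnorm(n)
  out <- ancova_fixed_plus_covariate(y, fixed, covariate)

  rss <- function(fit) sum(resid(fit)^2)
  full <- lm(y ~ fixed + covariate)
  no_f <- lm(y ~ covariate)
  no_c <- lm(y ~ fixed)
  f_factor <- (rss(no_f) - rss(full)) / (rss(full) / (n - 3))
  f_cov <- (rss(no_c) - rss(full)) / (rss(full) / (n - 3))
  expect_equal(out$factor$statistic, f_factor, tolerance = 1e-10)
  expect_equal(out$covariate$statistic, f_cov, tolerance = 1e-10)
  expect_equal(out$factor$df, c(1, n - 3))

  # response driven by the covariate alone: covariate dominates and the
  # factor coefficient vanishes
  y2 <- 2 * covariate + rnorm(n, sd = 1e-3)
  out2 <- ancova_fixed_plus_covariate(y2, fixed, covariate)
  expect_gt(out2$covariate$statistic, 1e4 * max(out2$factor$statistic, 1))

  expect_error(ancova_fixed_plus_covariate(y, rep("a", n), covariate),
               "2 levels")
})

test_that("ANCOVA with an orthogonal covariate reduces to the adjusted group test", {
  set.seed(8)
  n <- 20
  fixed <- rep(c("a", "b"), each = n / 2)
  covariate <- rnorm(n)
  covariate <- resid(lm(covariate ~ fixed)) # exactly orthogonal to the factor
  y <- 1.5 * (fixed == "b") + 0.7 * covariate + rnorm(n)
  out <- ancova_fixed_plus_covariate(y, fixed, covariate)
  y_adj <- resid(lm(y ~ covariate))
  tt <- two_sample_t(y_adj[fixed == "a"], y_adj[fixed == "b"])
  # same effect estimate; F ~ t^2 up to the differing residual df
  expect_equal(out$factor$statistic, tt$statistic^2 * (n - 3) / (n - 2),
               tolerance = 1e-8)
})

test_that("JZS Bayes factor matches independent quadrature oracles", {
  # two-sided oracle: fine trapezoid grid over the g-mixture representation
  jzs_g_oracle <- function(t, n1, n2, r = 0.707) {
    n_eff <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
    lg <- seq(-12, 12, length.out = 40001)
    g <- exp(lg)
    f <- (1 + n_eff * g * r^2)^(-1 / 2) *
      (1 + t^2 / (nu * (1 + n_eff * g * r^2)))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g)) * g # du = g dlg
    num <- sum((f[-1] + f[-length(f)]) / 2 * diff(lg))
    num / (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  for (tt in c(0, 0.47, 1.3, 2.5)) {
    ours <- jzs_bayes_factor_t(tt, 32, 24)
    oracle <- jzs_g_oracle(tt, 32, 24)
    expect_equal(ours, oracle, tolerance = 5e-4 * oracle)
  }

  # one-sided oracle: trapezoid over effect size with the half-Cauchy prior
  jzs_d_oracle <- function(t, n1, n2, r = 0.707, side = -1) {
    n_eff <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
    d <- side * seq(1e-6, 60, length.out = 60001)
    f <- suppressWarnings(dt(t, nu, ncp = d * sqrt(n_eff))) *
      2 * dcauchy(d, 0, r)
    sum((f[-1] + f[-length(f)]) / 2 * abs(diff(d))) / dt(t, nu)
  }
  bf_less <- jzs_bayes_factor_t(0.47, 32, 24, alternative = "less")
  expect_equal(bf_less, jzs_d_oracle(0.47, 32, 24, side = -1),
               tolerance = 1e-3 * bf_less)

  # prior decomposition: two-sided is the mean of the one-sided factors
  bf2 <- jzs_bayes_factor_t(0.47, 32, 24)
  bf_gr <- jzs_bayes_factor_t(0.47, 32, 24, alternative = "greater")
  expect_equal(bf2, (bf_gr + bf_less) / 2, tolerance = 1e-6)

  # t = 0 favours the null; |t| monotonicity
  expect_lt(jzs_bayes_factor_t(0, 20, 20), 1)
  bfs <- vapply(c(0, 0.5, 1, 2, 3), jzs_bayes_factor_t, numeric(1),
                n1 = 15, n2 = 15)
  expect_true(all(diff(bfs) > 0))

  # one-sample variant uses df = n - 1
  expect_gt(jzs_bayes_factor_t(3, 20), 1)
})

test_that("PCA of pairwise distances matches the covariance eigensolver", {
  # rank-one table: one component, uniform loadings
  base <- rnorm(15)
  m1 <- matrix(base, 15, 5)
  colnames(m1) <- paste0("d", 1:5)
  p1 <- pca_pairwise_distances(m1)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-10)
  l1 <- abs(p1$loadings$PC1)
  expect_equal(l1, rep(1 / sqrt(5), 5), tolerance = 1e-10)

  # orthogonal two-block structure: leading components align with blocks
  set.seed(9)
  f1 <- rnorm(40); f2 <- rnorm(40)
  m2 <- cbind(d1 = 3 * f1, d2 = 3 * f1, d3 = f2, d4 = f2, d5 = f2)
  p2 <- pca_pairwise_distances(m2)
  expect_gt(sum(abs(p2$loadings$PC1[1:2])), sum(abs(p2$loadings$PC1[3:5])))
  expect_gt(sum(abs(p2$loadings$PC2[3:5])), sum(abs(p2$loadings$PC2[1:2])))

  # random table vs brute-force eigendecomposition of the covariance
  m3 <- matrix(rnorm(100), 20, 5)
  colnames(m3) <- paste0("d", 1:5)
  p3 <- pca_pairwise_distances(m3)
  eg <- eigen(cov(m3), symmetric = TRUE)
  expect_equal(p3$prcomp$sdev^2 * (19 / 19), eg$values, tolerance = 1e-9)
  for (k in 1:5) {
    expect_equal(abs(p3$loadings[[paste0("PC", k)]]), abs(eg$vectors[, k]),
                 tolerance = 1e-8)
  }
})

test_that("stat containers tidy into one-row tibbles", {
  r <- two_sample_t(rnorm(10), rnorm(10))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("method", "statistic", "df1", "p_value") %in% names(td)))
  expect_identical(glance(r), td)
})
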