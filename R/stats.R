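#' Statistical result container
#'
#' Lightweight container for the package's statistics layer, with broom-style
#' [generics::tidy()] and [generics::glance()] methods.
#'
#' @param statistic Test statistic (t, z, F, or r).
#' @param df Degrees of freedom (scalar or length-2 for F).
#' @param p_value Two- or one-sided p value as documented per test.
#' @param method Label of the procedure.
#' @param estimate Optional effect estimate.
#' @param ci Optional length-2 confidence interval.
#' @param bf10 Optional Bayes factor (alternative over null).
#' @param extra Optional named list of method-specific fields.
#' @return Object of class `prosrsa_stat`.
#' @export
prosrsa_stat <- function(statistic, df, p_value, method,
                         estimate = NULL, ci = NULL, bf10 = NULL,
                         extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  if (!is.null(bf10)) stopifnot(bf10 > 0)
  structure(
    list(statistic = statistic, df = df, p_value = p_value, method = method,
         estimate = estimate, ci = ci, bf10 = bf10, extra = extra),
    class = "prosrsa_stat"
  )
}

#' @export
print.prosrsa_stat <- function(x, ...) {
  df_txt <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, df_txt, x$p_value))
  if (!is.null(x$estimate)) cat(sprintf("  estimate = %.4g\n", x$estimate))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI [%.4g, %.4g]\n", x$ci[1], x$ci[2]))
  }
  if (!is.null(x$bf10)) cat(sprintf("  BF10 = %.4g\n", x$bf10))
  invisible(x)
}

#' @export
tidy.prosrsa_stat <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    estimate = if (is.null(x$estimate)) NA_real_ else x$estimate,
    statistic = x$statistic,
    df1 = x$df[1],
    df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
    p_value = x$p_value,
    conf_low = if (is.null(x$ci)) NA_real_ else x$ci[1],
    conf_high = if (is.null(x$ci)) NA_real_ else x$ci[2],
    bf10 = if (is.null(x$bf10)) NA_real_ else x$bf10
  )
}

#' @export
glance.prosrsa_stat <- function(x, ...) tidy.prosrsa_stat(x)

#' Pooled-variance two-sample t test
#'
#' Two-tailed Student t test assuming equal variances, so
#' `df = n_a + n_b - 2` (the reporting convention used for all group
#' comparisons here).
#'
#' @param a,b Numeric vectors for the two groups.
#' @return A [prosrsa_stat()] with the mean difference `a - b` as estimate.
#' @export
two_sample_t <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # degenerate but well-defined null case
    return(prosrsa_stat(0, length(a) + length(b) - 2, 1,
                        "two-sample t (pooled variance)", estimate = 0))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  prosrsa_stat(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    method = "two-sample t (pooled variance)",
    estimate = unname(ht$estimate[1] - ht$estimate[2]),
    ci = unname(ht$conf.int)
  )
}

#' One-sample t test against a reference value
#'
#' Used for the own-prosthesis normalised distances, where the null value 1
#' means "no difference from the control baseline".
#'
#' @param x Numeric vector.
#' @param mu Null value (default 1).
#' @return A [prosrsa_stat()].
#' @export
one_sample_t_vs <- function(x, mu = 1) {
  if (stats::sd(x) == 0 && mean(x) == mu) {
    return(prosrsa_stat(0, length(x) - 1, 1, paste0("one-sample t vs ", mu),
                        estimate = mu))
  }
  ht <- stats::t.test(x, mu = mu)
  prosrsa_stat(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, method = paste0("one-sample t vs ", mu),
    estimate = unname(ht$estimate), ci = unname(ht$conf.int)
  )
}

#' Pearson correlation with a seeded percentile bootstrap CI
#'
#' Two-tailed Pearson correlation with the analytic t-based p value
#' (`df = n - 2`) and a percentile confidence interval over paired
#' resamples.
#'
#' @param x,y Numeric vectors.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed for the resampling (mandatory for
#'   reproducibility).
#' @param conf_level CI coverage.
#' @return A [prosrsa_stat()] with `r` as estimate and the bootstrap CI.
#' @export
pearson_r_bootstrap <- function(x, y, n_boot = 10000, seed = 1L,
                                conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ht <- stats::cor.test(x, y, method = "pearson")
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(x), replace = TRUE)
      suppressWarnings(stats::cor(x[idx], y[idx]))
    }, numeric(1))
  })
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2),
                               na.rm = TRUE))
  prosrsa_stat(
    statistic = unname(ht$estimate), df = unname(ht$parameter),
    p_value = ht$p.value, method = "Pearson r (percentile bootstrap CI)",
    estimate = unname(ht$estimate), ci = ci,
    extra = list(n_boot = n_boot, seed = seed)
  )
}

#' Compare two dependent correlations sharing one variable
#'
#' Steiger's Z1* test for the difference between `r_xy` and `r_xz` when both
#' correlations share variable x (here, prosthesis usage): the two
#' correlations are Fisher z transformed and their difference is scaled using
#' the covariance term evaluated at the pooled correlation
#' `r_bar = (r_xy + r_xz) / 2`.
#'
#' @param r_xy,r_xz The two correlations being compared.
#' @param r_yz Correlation between the two non-shared variables (must come
#'   from the data).
#' @param n Sample size.
#' @return A [prosrsa_stat()] with a z statistic and two-sided p.
#' @export
compare_dependent_correlations <- function(r_xy, r_xz, r_yz, n) {
  rs <- c(r_xy, r_xz, r_yz)
  if (any(abs(rs) >= 1)) stop("correlations must be in (-1, 1)", call. = FALSE)
  cm <- matrix(c(1, r_xy, r_xz,
                 r_xy, 1, r_yz,
                 r_xz, r_yz, 1), 3, 3)
  if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("inconsistent correlation triple (not positive semidefinite)",
         call. = FALSE)
  }
  stopifnot(n > 3)
  z1 <- atanh(r_xy)
  z2 <- atanh(r_xz)
  r_bar <- (r_xy + r_xz) / 2
  psi <- r_yz * (1 - 2 * r_bar^2) -
    0.5 * r_bar^2 * (1 - 2 * r_bar^2 - r_yz^2)
  c_bar <- psi / (1 - r_bar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * c_bar))
  prosrsa_stat(
    statistic = z, df = Inf,
    p_value = 2 * stats::pnorm(-abs(z)),
    method = "Steiger Z1* (dependent correlations, shared variable)",
    estimate = r_xy - r_xz
  )
}

#' ANCOVA with one two-level factor and one covariate
#'
#' Fits `y ~ factor + covariate` with sum-to-zero contrasts and reports the
#' partial (Type III) F tests for the factor and the covariate, each on
#' `(1, n - 3)` degrees of freedom.
#'
#' @param y Response vector.
#' @param fixed Two-level factor (or coercible).
#' @param covariate Numeric covariate.
#' @return Named list of two [prosrsa_stat()]s: `factor` and `covariate`.
#' @export
ancova_fixed_plus_covariate <- function(y, fixed, covariate) {
  fixed <- factor(fixed)
  if (nlevels(fixed) != 2) stop("fixed must have exactly 2 levels", call. = FALSE)
  dat <- data.frame(y = y, fixed = fixed, covariate = covariate)
  fit <- stats::lm(y ~ fixed + covariate, data = dat,
                   contrasts = list(fixed = "contr.sum"))
  an <- car::Anova(fit, type = "III")
  res_df <- an["Residuals", "Df"]
  out <- lapply(c(factor = "fixed", covariate = "covariate"), function(term) {
    prosrsa_stat(
      statistic = an[term, "F value"], df = c(an[term, "Df"], res_df),
      p_value = an[term, "Pr(>F)"],
      method = paste0("ANCOVA Type III F (", term, ")")
    )
  })
  out
}

#' JZS default-prior Bayes factor for a t test
#'
#' Evidence ratio BF10 for the default Bayesian t test: the alternative puts
#' a Cauchy prior (scale `cauchy_scale`, default 0.707) on the standardised
#' effect size, and the marginal likelihood is obtained by integrating the
#' noncentral-t likelihood of the observed t statistic over that prior. For
#' one-sided alternatives the prior is the half-Cauchy on the corresponding
#' sign (so the two-sided factor is the average of the two one-sided
#' factors). Values below 1/3 are conventionally read as substantial support
#' for the null.
#'
#' @param t Observed t statistic.
#' @param n1 First (or only) group size.
#' @param n2 Second group size for the two-sample case, `NULL` for one
#'   sample.
#' @param cauchy_scale Cauchy prior scale on effect size.
#' @param alternative `"two_sided"`, `"greater"`, or `"less"` (direction of
#'   the effect-size prior).
#' @return Scalar BF10.
#' @export
jzs_bayes_factor_t <- function(t, n1, n2 = NULL, cauchy_scale = 0.707,
                               alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.finite(t), cauchy_scale > 0, n1 >= 2)
  if (is.null(n2)) {
    n_eff <- n1
    nu <- n1 - 1
  } else {
    stopifnot(n2 >= 2)
    n_eff <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
  }
  lik <- function(delta) {
    suppressWarnings(stats::dt(t, df = nu, ncp = delta * sqrt(n_eff)))
  }
  integrand <- function(delta) {
    lik(delta) * stats::dcauchy(delta, 0, cauchy_scale)
  }
  num <- switch(
    alternative,
    two_sided = stats::integrate(integrand, -Inf, Inf,
                                 rel.tol = 1e-8, stop.on.error = FALSE),
    greater = stats::integrate(function(d) 2 * integrand(d), 0, Inf,
                               rel.tol = 1e-8, stop.on.error = FALSE),
    less = stats::integrate(function(d) 2 * integrand(d), -Inf, 0,
                            rel.tol = 1e-8, stop.on.error = FALSE)
  )
  if (num$message != "OK" && num$abs.error > 1e-6 * max(num$value, 1e-12)) {
    stop("quadrature did not converge: ", num$message,
         " (abs.error = ", signif(num$abs.error, 3), ")", call. = FALSE)
  }
  num$value / stats::dt(t, df = nu)
}

#' PCA of per-subject pairwise distances
#'
#' Principal components of a `subjects x distances` table (column-centred,
#' unscaled), used to explore which pairwise distances carry the
#' between-subject variance.
#'
#' @param distance_table Data frame or matrix; columns are pairwise
#'   distances, rows subjects.
#' @return List with `loadings` (tibble: one row per distance, one column per
#'   component), `explained_variance` (proportion per component), and the
#'   underlying `prcomp` object.
#' @export
pca_pairwise_distances <- function(distance_table) {
  m <- as.matrix(distance_table)
  stopifnot(nrow(m) >= 2)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(
    loadings = dplyr::bind_cols(
      tibble::tibble(distance = colnames(m)),
      tibble::as_tibble(pc$rotation)
    ),
    explained_variance = ev / sum(ev),
    prcomp = pc
  )
}
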