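#' Estimate the voxel noise covariance from GLM residuals
#'
#' Per-run sample covariances of the residual timeseries are averaged across
#' runs and then shrunk towards their diagonal, following standard practice
#' for multivariate noise normalisation of fMRI patterns: the off-diagonal
#' entries are multiplied by `1 - lambda`, with the shrinkage weight chosen
#' analytically (Ledoit-Wolf/Schafer-Strimmer style) as the ratio of the
#' summed sampling variances of the off-diagonal covariances to their summed
#' squares, clipped to `[0, 1]`. The whitener is the inverse symmetric square
#' root of the shrunk covariance.
#'
#' @param residuals List of `timepoints x voxels` residual matrices, one per
#'   run (a single matrix is treated as one run).
#' @param shrinkage Optional shrinkage weight in `[0, 1]` to force instead of
#'   the analytic estimate (`1` = fully diagonal, `0` = raw average).
#' @return A `noise_model`: list with `covariance`, `shrinkage_lambda`, and
#'   `whitener` (`W` with `W %*% covariance %*% t(W)` = identity).
#' @export
estimate_noise_covariance <- function(residuals, shrinkage = NULL) {
  if (is.matrix(residuals)) residuals <- list(residuals)
  stopifnot(length(residuals) >= 1)
  p <- ncol(residuals[[1]])
  for (r in seq_along(residuals)) {
    if (nrow(residuals[[r]]) < 2) {
      stop("run ", r, " has fewer than 2 residual timepoints", call. = FALSE)
    }
    if (ncol(residuals[[r]]) != p) {
      stop("runs disagree in voxel count", call. = FALSE)
    }
  }
  covs <- lapply(residuals, function(x) {
    xc <- scale(x, center = TRUE, scale = FALSE)
    crossprod(xc) / (nrow(x) - 1)
  })
  s <- Reduce(`+`, covs) / length(covs)
  v <- diag(s)
  if (any(v <= 0)) {
    stop("zero-variance voxel(s): ", paste(which(v <= 0), collapse = ", "),
         call. = FALSE)
  }
  lambda <- if (is.null(shrinkage)) shrinkage_weight(residuals, s) else shrinkage
  stopifnot(lambda >= 0, lambda <= 1)
  shrunk <- (1 - lambda) * s
  diag(shrunk) <- v
  structure(
    list(covariance = shrunk, shrinkage_lambda = lambda,
         whitener = inv_sqrtm(shrunk)),
    class = "noise_model"
  )
}

# Analytic shrinkage-towards-diagonal weight: sum of estimated sampling
# variances of the off-diagonal covariance entries over the sum of their
# squares, pooling timepoints across runs (each run centred separately).
shrinkage_weight <- function(residuals, s) {
  p <- ncol(s)
  xc <- do.call(rbind, lapply(residuals, function(x) {
    scale(x, center = TRUE, scale = FALSE)
  }))
  n <- nrow(xc)
  # with w_tij = x_ti * x_tj: var-hat of s_ij = n^2/(n-1)^3 * (mean(w^2) -
  # mean(w)^2), the standard analytic form computed via product moments
  w_bar <- crossprod(xc) / n
  w2 <- crossprod(xc^2) / n
  var_s <- n^2 / (n - 1)^3 * (w2 - w_bar^2)
  off <- upper.tri(s)
  denom <- sum(s[off]^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(var_s[off]) / denom))
}

# Inverse symmetric square root via eigendecomposition.
inv_sqrtm <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) {
    stop("covariance is not positive definite", call. = FALSE)
  }
  e$vectors %*% diag(1 / sqrt(e$values), nrow(m)) %*% t(e$vectors)
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model>", nrow(x$covariance), "voxels, shrinkage lambda =",
      signif(x$shrinkage_lambda, 3), "\n")
  invisible(x)
}

#' Multivariate noise normalisation of beta patterns
#'
#' Right-multiplies every run-and-condition pattern by the whitener so that
#' noisier (and correlated) voxels are down-weighted; after prewhitening the
#' residual covariance is the identity. Whitening with an identity covariance
#' is the identity map.
#'
#' @param betas Array `runs x conditions x voxels`.
#' @param noise A `noise_model` from [estimate_noise_covariance()].
#' @return Array of the same shape with whitened patterns.
#' @export
prewhiten <- function(betas, noise) {
  stopifnot(inherits(noise, "noise_model"),
            is.array(betas), length(dim(betas)) == 3)
  if (dim(betas)[3] != nrow(noise$covariance)) {
    stop("voxel dimension mismatch: betas have ", dim(betas)[3],
         " voxels, noise model has ", nrow(noise$covariance), call. = FALSE)
  }
  out <- betas
  for (r in seq_len(dim(betas)[1])) {
    out[r, , ] <- betas[r, , ] %*% noise$whitener
  }
  out
}
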