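# Build an rdm for the four main conditions from named pairwise distances.
# Names use initials: h = hands, c = cosmetic, a = active, t = tools.
toy_rdm <- function(hc, ha, ht, ca, ct, at, own_h = NULL, own_t = NULL,
                    own_c = 0, own_a = 0) {
  cn <- c("hands", "cosmetic_prosthesis", "active_prosthesis", "tools")
  m <- matrix(0, 4, 4, dimnames = list(cn, cn))
  m["hands", "cosmetic_prosthesis"] <- m["cosmetic_prosthesis", "hands"] <- hc
  m["hands", "active_prosthesis"] <- m["active_prosthesis", "hands"] <- ha
  m["hands", "tools"] <- m["tools", "hands"] <- ht
  m["cosmetic_prosthesis", "active_prosthesis"] <-
    m["active_prosthesis", "cosmetic_prosthesis"] <- ca
  m["cosmetic_prosthesis", "tools"] <- m["tools", "cosmetic_prosthesis"] <- ct
  m["active_prosthesis", "tools"] <- m["tools", "active_prosthesis"] <- at
  if (!is.null(own_h)) {
    m <- rbind(cbind(m, own_prosthesis = c(own_h, own_c, own_a, own_t)),
               own_prosthesis = c(own_h, own_c, own_a, own_t, 0))
  }
  rdm(m, rownames(m))
}

# An rdm with every off-diagonal distance equal to d.
equal_rdm <- function(d = 1) toy_rdm(d, d, d, d, d, d)

# Beta array builder: list of runs, each a conditions x voxels matrix.
betas_from_runs <- function(runs, conditions = NULL) {
  n_runs <- length(runs)
  n_cond <- nrow(runs[[1]])
  n_vox <- ncol(runs[[1]])
  if (is.null(conditions)) {
    conditions <- rownames(runs[[1]])
    if (is.null(conditions)) conditions <- paste0("cond", seq_len(n_cond))
  }
  out <- array(NA_real_, c(n_runs, n_cond, n_vox),
               dimnames = list(paste0("run", seq_len(n_runs)), conditions, NULL))
  for (r in seq_len(n_runs)) out[r, , ] <- runs[[r]]
  out
}

# Independent brute-force crossnobis oracle written as plain loops over
# folds; deliberately shares no code with the package implementation.
crossnobis_oracle <- function(betas) {
  n_runs <- dim(betas)[1]
  n_cond <- dim(betas)[2]
  n_vox <- dim(betas)[3]
  d <- matrix(0, n_cond, n_cond)
  for (a in seq_len(n_cond)) {
    for (b in seq_len(n_cond)) {
      if (a == b) next
      total <- 0
      for (f in seq_len(n_runs)) {
        train <- rep(0, n_vox)
        for (r in setdiff(seq_len(n_runs), f)) {
          train <- train + (betas[r, a, ] - betas[r, b, ])
        }
        train <- train / (n_runs - 1)
        test <- betas[f, a, ] - betas[f, b, ]
        total <- total + sum(train * test) / n_vox
      }
      d[a, b] <- total / n_runs
    }
  }
  dimnames(d) <- list(dimnames(betas)[[2]], dimnames(betas)[[2]])
  d
}

# Tiny simulation configs used across tests.
tiny_config <- function(seed = 1, ...) {
  sim_config(n_controls = 4, n_users = 6, n_runs = 2, n_voxels = 16,
             n_residual_timepoints = 30, noise_variance = 1,
             spatial_correlation_length = 1.5, seed = seed, ...)
}

# RDMs for all subjects of a cohort computed on the full candidate set
# (no ROI selection), for tests that do not exercise the ROI stage.
cohort_rdms <- function(cohort, shrinkage = NULL) {
  lapply(cohort$subjects, function(s) {
    noise <- estimate_noise_covariance(s$residuals, shrinkage = shrinkage)
    crossnobis_rdm(prewhiten(s$betas, noise))
  })
}
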