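#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. The defaults mirror
#' the study design being emulated: 24 two-handed controls and 32 one-handed
#' prosthesis users, 4 functional runs, a 500-voxel region of interest, and
#' spatially correlated run-level noise shared between the beta estimates and
#' the GLM residuals (so that noise-covariance estimation downstream is
#' consistent with the generating process).
#'
#' @param n_controls,n_users Group sizes.
#' @param n_runs Number of functional runs (at least 2; cross-validated
#'   distances need folds).
#' @param n_voxels Region-of-interest size (total across both hemispheres).
#' @param n_residual_timepoints Residual timepoints per run used for noise
#'   covariance estimation.
#' @param noise_variance Marginal noise variance per voxel (arbitrary beta
#'   units squared).
#' @param spatial_correlation_length Length scale (in voxel-index units) of
#'   the squared-exponential noise covariance; `0` gives independent voxels.
#' @param candidate_factor The candidate voxel set handed to ROI selection is
#'   `candidate_factor * n_voxels` voxels, split evenly between hemispheres.
#' @param seed Integer master seed; every downstream draw derives from it.
#' @param usage Parameters of the usage-sampling model: `type_probs`, the
#'   primary-prosthesis class probabilities (cosmetic, mechanical,
#'   myoelectric, none, hybrid), and `pal_p_scale`, the per-item success
#'   probability of the activity log at maximal wear propensity.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_controls = 24,
                       n_users = 32,
                       n_runs = 4,
                       n_voxels = 500,
                       n_residual_timepoints = 100,
                       noise_variance = 1,
                       spatial_correlation_length = 2,
                       candidate_factor = 1.2,
                       seed = 1L,
                       usage = list(
                         type_probs = c(cosmetic = 0.40, mechanical = 0.25,
                                        myoelectric = 0.16, none = 0.16,
                                        hybrid = 0.03),
                         pal_p_scale = 0.65
                       )) {
  stopifnot(n_controls >= 0, n_users >= 0, n_voxels >= 2,
            n_residual_timepoints >= 2, candidate_factor >= 1)
  if (n_runs < 2) {
    stop("n_runs must be >= 2: leave-one-run-out cross-validation needs folds",
         call. = FALSE)
  }
  if (!is.finite(noise_variance) || noise_variance < 0) {
    stop("noise_variance must be a non-negative finite scalar", call. = FALSE)
  }
  if (spatial_correlation_length < 0) {
    stop("spatial_correlation_length must be non-negative", call. = FALSE)
  }
  structure(
    list(
      n_controls = as.integer(n_controls), n_users = as.integer(n_users),
      n_runs = as.integer(n_runs), n_voxels = as.integer(n_voxels),
      n_residual_timepoints = as.integer(n_residual_timepoints),
      noise_variance = noise_variance,
      spatial_correlation_length = spatial_correlation_length,
      candidate_factor = candidate_factor,
      seed = as.integer(seed),
      usage = usage
    ),
    class = "sim_config"
  )
}

#' Squared-exponential voxel noise covariance
#'
#' `K[i, j] = variance * exp(-(i - j)^2 / (2 * length_scale^2))`, with a tiny
#' diagonal jitter so the Cholesky factor always exists. A zero length scale
#' gives independent voxels.
#'
#' @param n_voxels Matrix dimension.
#' @param variance Marginal variance.
#' @param length_scale Correlation length in voxel-index units.
#' @return `n_voxels x n_voxels` positive-definite covariance matrix.
#' @export
sq_exp_covariance <- function(n_voxels, variance = 1, length_scale = 2) {
  if (length_scale <= 0 || variance == 0) {
    return(diag(variance, n_voxels))
  }
  idx <- seq_len(n_voxels)
  k <- variance * exp(-outer(idx, idx, "-")^2 / (2 * length_scale^2))
  k + diag(1e-8 * variance, n_voxels)
}

# Draw n rows from N(0, K) given the upper Cholesky factor of K.
draw_mvn <- function(n, chol_k) {
  z <- matrix(stats::rnorm(n * ncol(chol_k)), n, ncol(chol_k))
  z %*% chol_k
}

#' Simulate one subject's beta patterns and residuals
#'
#' Generates run-wise condition beta patterns as true means plus spatially
#' correlated Gaussian noise, and residual timeseries drawn from the same
#' noise covariance, plus a localizer statistic per voxel (planted signal
#' energy plus unit noise) for ROI selection.
#'
#' @param true_means Either a `conditions x voxels` matrix of true mean
#'   patterns, or a list with elements `control` and `user` (matrices of the
#'   same shape), in which case the subject's means are the linear
#'   interpolation `control + usage * (user - control)` in pattern space.
#' @param config A [sim_config()].
#' @param usage Interpolation weight in `[0, 1]` (only used for list means).
#' @param group Group label stored with the subject.
#' @param seed Integer seed; identical seeds give bit-identical subjects.
#' @return A `synthetic_subject`: list with `betas` (array
#'   `runs x conditions x voxels`), `residuals` (list of
#'   `timepoints x voxels` matrices, one per run), `localizer_stat`,
#'   `group`, and `usage_weight`.
#' @export
simulate_subject <- function(true_means, config, usage = 0,
                             group = "control", seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.list(true_means) && !is.matrix(true_means)) {
    stopifnot(all(c("control", "user") %in% names(true_means)))
    w <- min(max(usage, 0), 1)
    means <- true_means$control + w * (true_means$user - true_means$control)
  } else {
    means <- as.matrix(true_means)
  }
  n_cond <- nrow(means)
  n_vox <- ncol(means)
  n_runs <- config$n_runs
  ck <- if (config$noise_variance > 0) {
    chol(sq_exp_covariance(n_vox, config$noise_variance,
                           config$spatial_correlation_length))
  } else {
    diag(0, n_vox)
  }
  betas <- array(NA_real_, dim = c(n_runs, n_cond, n_vox),
                 dimnames = list(paste0("run", seq_len(n_runs)),
                                 rownames(means), NULL))
  residuals <- vector("list", n_runs)
  withr::with_seed(seed, {
    for (r in seq_len(n_runs)) {
      betas[r, , ] <- means +
        if (config$noise_variance > 0) draw_mvn(n_cond, ck) else 0
      residuals[[r]] <-
        if (config$noise_variance > 0) {
          draw_mvn(config$n_residual_timepoints, ck)
        } else {
          matrix(0, config$n_residual_timepoints, n_vox)
        }
    }
    localizer <- colSums(means^2) / max(mean(colSums(means^2)), 1e-12) +
      stats::rnorm(n_vox)
  })
  structure(
    list(betas = betas, residuals = residuals, localizer_stat = localizer,
         group = group, usage_weight = if (is.list(true_means)) usage else NA_real_),
    class = "synthetic_subject"
  )
}

# Orthogonal Procrustes: rotation R minimising ||A %*% R - B||_F.
procrustes_rotation <- function(a, b) {
  s <- svd(t(a) %*% b)
  s$u %*% t(s$v)
}

# Sample per-user usage raw measurements (wear ratings per prosthesis type
# and 27 activity-log items) from a latent usage propensity.
sample_usage_records <- function(n_users, usage_pars) {
  probs <- usage_pars$type_probs
  types <- sample(names(probs), n_users, replace = TRUE, prob = probs)
  theta <- stats::rbeta(n_users, 2, 1.3) # usage propensity of actual users
  wear <- matrix(0L, n_users, 3,
                 dimnames = list(NULL, c("cosmetic", "mechanical", "myoelectric")))
  pal_items <- matrix(0L, n_users, 27)
  for (i in seq_len(n_users)) {
    if (types[i] == "none") next
    w <- max(1L, as.integer(round(theta[i] * 5)))
    if (types[i] == "hybrid") {
      pair <- sample(colnames(wear), 2)
      wear[i, pair] <- w
    } else {
      wear[i, types[i]] <- w
      # occasional secondary prosthesis, worn less
      if (stats::runif(1) < 0.2) {
        other <- sample(setdiff(colnames(wear), types[i]), 1)
        wear[i, other] <- sample.int(max(w - 1L, 1L), 1)
      }
    }
    pal_items[i, ] <- stats::rbinom(27, 2, usage_pars$pal_p_scale * theta[i])
  }
  colnames(pal_items) <- sprintf("pal_item_%02d", 1:27)
  list(wear = wear, pal_items = pal_items)
}

#' Simulate a full synthetic cohort
#'
#' Generates controls with the control geometry and prosthesis users whose
#' condition-mean patterns are linearly interpolated between the control
#' geometry and the prosthesis-cluster geometry, with interpolation weight
#' `usage_coupling * standardised usage` (usage scores min-max standardised
#' across the user group). Usage itself is sampled as raw wear ratings and
#' activity-log items and pushed through the same composite scoring chain as
#' real data ([pal_score()], [wear_frequency()], [usage_score()],
#' [classify_primary()]), so the generator exercises the usage module end to
#' end. Users (except non-users and hybrids) also receive an
#' `own_prosthesis` condition whose distance from hands is planted at
#' `own_hand_scale` times the matched generic prosthesis distance at full
#' usage weight.
#'
#' @param config A [sim_config()].
#' @param control_template,user_template [geometry_template()]s sharing the
#'   same condition names. The user template's embedding is Procrustes-aligned
#'   to the control embedding before interpolation.
#' @param include_own Add the own-prosthesis condition for eligible users.
#' @param own_hand_scale Planted multiplicative displacement of the own
#'   prosthesis from hands relative to the control baseline (1 = no shift).
#' @return A `prosrsa_cohort`: list with `subjects` (named list of
#'   `synthetic_subject`), `metadata` (tibble, one row per subject),
#'   `hemisphere` (candidate-voxel hemisphere labels), `n_candidate`, and the
#'   two templates.
#' @export
simulate_cohort <- function(config = sim_config(),
                            control_template = default_control_template(),
                            user_template = default_user_template(),
                            include_own = TRUE,
                            own_hand_scale = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(control_template$condition_names,
                 user_template$condition_names)) {
    stop("templates must share condition_names", call. = FALSE)
  }
  n_candidate <- 2L * as.integer(ceiling(config$n_voxels * config$candidate_factor / 2))
  hemisphere <- rep(c("left", "right"), each = n_candidate / 2)

  # shared scale: per-voxel-normalised crossnobis of the full candidate set
  # then approximates the template's squared distances
  scale <- sqrt(n_candidate)
  ctrl_means <- embed_geometry(control_template, n_candidate,
                               seed = config$seed) * scale
  user_means <- embed_geometry(user_template, n_candidate,
                               seed = config$seed + 1L) * scale
  user_means <- user_means %*% procrustes_rotation(user_means, ctrl_means)
  rownames(user_means) <- user_template$condition_names
  # Template distances are defined in noise-normalised (Mahalanobis) units:
  # colouring the means by the noise correlation square root makes the
  # whitened geometry reproduce the template (for unit noise variance)
  # instead of being distorted direction-dependently by prewhitening.
  if (config$spatial_correlation_length > 0) {
    corr <- sq_exp_covariance(n_candidate, 1, config$spatial_correlation_length)
    e <- eigen(corr, symmetric = TRUE)
    color <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n_candidate) %*%
      t(e$vectors)
    ctrl_means <- ctrl_means %*% color
    user_means <- user_means %*% color
  }

  n_total <- config$n_controls + config$n_users
  withr::with_seed(config$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_total + 1L)
    usage_raw <- sample_usage_records(config$n_users, config$usage)
    subgroup <- sample(rep_len(c("congenital", "acquired"), config$n_users))
    own_hand_like_mech <- stats::rbinom(config$n_users, 1, 0.15)
  })

  pal <- apply(usage_raw$pal_items, 1, pal_score)
  wear_freq <- apply(usage_raw$wear, 1, wear_frequency)
  uscore <- if (config$n_users >= 2 &&
                stats::var(pal) > 0 && stats::var(wear_freq) > 0) {
    usage_score(pal, wear_freq)
  } else {
    rep(0, config$n_users)
  }
  primary <- apply(usage_raw$wear, 1, classify_primary)
  u_rng <- range(uscore)
  u_std <- if (diff(u_rng) > 0) (uscore - u_rng[1]) / diff(u_rng) else rep(0, config$n_users)
  w_user <- pmin(pmax(user_template$usage_coupling * u_std, 0), 1)

  own_condition <- ifelse(primary %in% c("non_user", "hybrid"), NA_character_, primary)
  own_hand_like <- ifelse(is.na(own_condition), NA_integer_,
                          ifelse(own_condition == "mechanical",
                                 own_hand_like_mech, 1L))

  subjects <- vector("list", n_total)
  ids <- sprintf("S%02d", seq_len(n_total))
  group <- rep(c("control", "user"), c(config$n_controls, config$n_users))
  for (i in seq_len(n_total)) {
    if (group[i] == "control") {
      means <- ctrl_means
      w <- 0
    } else {
      u <- i - config$n_controls
      w <- w_user[u]
      means <- ctrl_means + w * (user_means - ctrl_means)
      if (include_own && !is.na(own_condition[u])) {
        matched <- if (own_condition[u] == "cosmetic") {
          "cosmetic_prosthesis"
        } else {
          "active_prosthesis"
        }
        baseline <- ctrl_means[matched, ]
        displaced <- ctrl_means["hands", ] +
          sqrt(own_hand_scale) * (baseline - ctrl_means["hands", ])
        own <- baseline + w * (displaced - baseline)
        means <- rbind(means, own_prosthesis = own)
      }
    }
    subjects[[i]] <- simulate_subject(means, config, group = group[i],
                                      seed = seeds[i])
  }
  names(subjects) <- ids

  metadata <- tibble::tibble(
    subject_id = ids,
    group = group,
    subgroup = c(rep(NA_character_, config$n_controls), subgroup),
    pal_score = c(rep(NA_real_, config$n_controls), pal),
    wear_frequency = c(rep(NA_real_, config$n_controls), wear_freq),
    usage_score = c(rep(NA_real_, config$n_controls), uscore),
    usage_weight = c(rep(0, config$n_controls), w_user),
    primary_class = c(rep(NA_character_, config$n_controls), primary),
    own_condition = c(rep(NA_character_, config$n_controls), own_condition),
    own_hand_like = c(rep(NA_integer_, config$n_controls), own_hand_like)
  )
  wear_tbl <- tibble::as_tibble(usage_raw$wear)
  names(wear_tbl) <- paste0("wear_", names(wear_tbl))
  pal_tbl <- tibble::as_tibble(usage_raw$pal_items)
  pad <- function(tbl) {
    na_block <- tbl[rep(NA_integer_, config$n_controls), ]
    dplyr::bind_rows(na_block, tbl)
  }
  metadata <- dplyr::bind_cols(metadata, pad(wear_tbl), pad(pal_tbl))

  structure(
    list(subjects = subjects, metadata = metadata, hemisphere = hemisphere,
         n_candidate = n_candidate, control_template = control_template,
         user_template = user_template, config = config),
    class = "prosrsa_cohort"
  )
}

#' @export
print.prosrsa_cohort <- function(x, ...) {
  cat("<prosrsa_cohort>", x$config$n_controls, "controls +", x$config$n_users,
      "users;", x$config$n_runs, "runs x", x$n_candidate,
      "candidate voxels\n")
  invisible(x)
}
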