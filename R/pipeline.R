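#' Pipeline configuration
#'
#' Bundles the options of every stage of the simulate -> ROI -> RDM ->
#' indices -> statistics pipeline. Every stochastic stage derives its draws
#' from the single `seed` carried by `sim`.
#'
#' @param sim A [sim_config()] for the synthetic cohort.
#' @param n_per_hemisphere ROI size per hemisphere (`NULL` = whole mask).
#' @param shrinkage Optional forced shrinkage weight (see
#'   [estimate_noise_covariance()]).
#' @param linkage Dendrogram linkage method.
#' @param pooling Residualisation pooling for the indices
#'   (`"pooled"`/`"by_group"`).
#' @param own_matching Own-prosthesis matching rule
#'   (`"type"`/`"hand_likeness"`).
#' @param active_variant Handling of subjects flagged as having viewed a
#'   different active exemplar (`"replace"`/`"exclude"`/`"none"`).
#' @param n_boot Bootstrap resamples for correlation CIs.
#' @param bf_scale Cauchy prior scale for Bayes factors.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_per_hemisphere = NULL,
                            shrinkage = NULL,
                            linkage = "average",
                            pooling = "pooled",
                            own_matching = "type",
                            active_variant = "none",
                            n_boot = 10000,
                            bf_scale = 0.707) {
  stopifnot(inherits(sim, "sim_config"))
  if (is.null(n_per_hemisphere)) {
    n_per_hemisphere <- as.integer(sim$n_voxels / 2)
  }
  structure(
    list(sim = sim, n_per_hemisphere = n_per_hemisphere,
         shrinkage = shrinkage, linkage = linkage, pooling = pooling,
         own_matching = own_matching, active_variant = active_variant,
         n_boot = n_boot, bf_scale = bf_scale),
    class = "pipeline_config"
  )
}

#' Per-subject RDM from candidate-voxel data
#'
#' Convenience wrapper chaining ROI restriction, noise-covariance estimation,
#' prewhitening, and the crossnobis RDM for one subject.
#'
#' @param subject A `synthetic_subject` (betas over the candidate voxel set).
#' @param roi A [select_top_voxels()] result.
#' @param shrinkage Optional forced shrinkage weight.
#' @return An [rdm()].
#' @export
subject_rdm <- function(subject, roi, shrinkage = NULL) {
  s <- subset_to_roi(subject, roi)
  noise <- estimate_noise_covariance(s$residuals, shrinkage = shrinkage)
  crossnobis_rdm(prewhiten(s$betas, noise))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a cohort, selects each subject's ROI from their localizer map,
#' estimates noise-normalised crossnobis RDMs, computes similarity indices
#' and own-prosthesis scores, builds group-mean dendrograms, and runs the
#' statistics layer (group comparisons of both indices, usage correlations,
#' their dependent-correlation comparison, the congenital/acquired ANCOVA,
#' own-prosthesis one-sample tests, and a Bayes factor for the
#' hand-similarity group test). Deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-simulated [simulate_cohort()] result (stage
#'   caching); simulated from `config$sim` when `NULL`.
#' @param out_dir Optional directory: per-stage outputs are written as
#'   CSV/JSON/Newick files.
#' @return A `prosrsa_report` list: `metadata`, `rdms`, `indices`,
#'   `own_scores`, `dendrograms` (per group), `stats` (tibble of tidied
#'   results), `mean_rdms`, and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$sim)
  }
  meta <- cohort$metadata

  rdms <- purrr::imap(cohort$subjects, function(s, id) {
    roi <- select_top_voxels(s$localizer_stat, cohort$hemisphere,
                             n_per_hemisphere = config$n_per_hemisphere)
    subject_rdm(s, roi, shrinkage = config$shrinkage)
  })

  # the index layer works on the four shared conditions
  main_rdms <- purrr::map(rdms, function(r) {
    keep <- intersect(rownames(r), main_conditions)
    rdm(unclass(r)[keep, keep], keep)
  })
  user_ids <- meta$subject_id[meta$group == "user"]
  ctrl_ids <- meta$subject_id[meta$group == "control"]
  if (config$active_variant != "none") {
    affected <- meta$subject_id[!is.na(meta$own_condition) &
                                  meta$own_condition == "myoelectric"]
    replaced <- replace_active_distances(main_rdms[user_ids], affected,
                                         variant = config$active_variant)
    main_rdms <- c(main_rdms[ctrl_ids], replaced)
  }
  indices <- compute_similarity_indices(
    main_rdms, meta[meta$subject_id %in% names(main_rdms), ],
    pooling = config$pooling
  )

  own <- own_prosthesis_scores(rdms[user_ids], rdms[ctrl_ids], meta,
                               matching = config$own_matching)

  grp_rdm <- list(
    control = mean_rdm(main_rdms[intersect(ctrl_ids, names(main_rdms))]),
    user = mean_rdm(main_rdms[intersect(user_ids, names(main_rdms))])
  )
  dendros <- suppressWarnings(
    purrr::map(grp_rdm, linkage_dendrogram, method = config$linkage)
  )

  stats_list <- pipeline_stats(indices, own, config)

  report <- structure(
    list(metadata = meta, rdms = rdms, indices = indices, own_scores = own,
         mean_rdms = grp_rdm, dendrograms = dendros, stats = stats_list,
         config = config),
    class = "prosrsa_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

pipeline_stats <- function(indices, own, config) {
  u <- indices[indices$group == "user", ]
  c_ <- indices[indices$group == "control", ]
  res <- list()
  res$hand_similarity_group <-
    two_sample_t(c_$hand_similarity_std, u$hand_similarity_std)
  res$prosthesis_similarity_group <-
    two_sample_t(c_$prosthesis_similarity_std, u$prosthesis_similarity_std)
  res$hand_similarity_group_bf <- prosrsa_stat(
    statistic = res$hand_similarity_group$statistic,
    df = res$hand_similarity_group$df,
    p_value = res$hand_similarity_group$p_value,
    method = "JZS BF (hand-similarity group, one-tailed vs observed)",
    bf10 = jzs_bayes_factor_t(
      res$hand_similarity_group$statistic, nrow(c_), nrow(u),
      cauchy_scale = config$bf_scale,
      alternative = if (res$hand_similarity_group$statistic >= 0) "less" else "greater"
    )
  )
  if (nrow(u) >= 4 && !all(is.na(u$usage_score))) {
    res$usage_vs_hand_similarity <- pearson_r_bootstrap(
      u$usage_score, u$hand_similarity_std,
      n_boot = config$n_boot, seed = config$sim$seed
    )
    res$usage_vs_prosthesis_similarity <- pearson_r_bootstrap(
      u$usage_score, u$prosthesis_similarity_std,
      n_boot = config$n_boot, seed = config$sim$seed + 1L
    )
    r_idx <- stats::cor(u$hand_similarity_std, u$prosthesis_similarity_std)
    r_xy <- res$usage_vs_hand_similarity$estimate
    r_xz <- res$usage_vs_prosthesis_similarity$estimate
    if (all(abs(c(r_xy, r_xz, r_idx)) < 1)) {
      res$dependent_correlation_comparison <- tryCatch(
        compare_dependent_correlations(r_xy, r_xz, r_idx, nrow(u)),
        error = function(e) NULL
      )
    }
    if (!all(is.na(u$subgroup)) && length(unique(u$subgroup)) == 2) {
      anc <- ancova_fixed_plus_covariate(
        u$prosthesis_similarity_std, u$subgroup, u$usage_score
      )
      res$subgroup_ancova_factor <- anc$factor
      res$subgroup_ancova_usage <- anc$covariate
    }
  }
  if (nrow(own) >= 3) {
    res$own_hand_vs_1 <- one_sample_t_vs(own$own_hand_normalized, 1)
    res$own_tool_vs_1 <- one_sample_t_vs(own$own_tool_normalized, 1)
  }
  res <- purrr::compact(res)
  dplyr::bind_cols(
    tibble::tibble(analysis = names(res)),
    dplyr::bind_rows(purrr::map(res, tidy.prosrsa_stat))
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(report$indices, file.path(out_dir, "indices.csv"),
                   row.names = FALSE)
  utils::write.csv(report$own_scores, file.path(out_dir, "own_scores.csv"),
                   row.names = FALSE)
  long <- dplyr::bind_rows(
    purrr::imap(report$rdms, ~ dplyr::mutate(tidy.rdm(.x), subject_id = .y))
  )
  utils::write.csv(long, file.path(out_dir, "rdms_long.csv"),
                   row.names = FALSE)
  writeLines(
    vapply(report$dendrograms, function(d) d$newick, character(1)),
    file.path(out_dir, "dendrograms.nwk")
  )
  jsonlite::write_json(report$stats, file.path(out_dir, "stats.json"),
                       dataframe = "rows", digits = NA, na = "null")
  invisible(out_dir)
}

#' @export
print.prosrsa_report <- function(x, ...) {
  cat("<prosrsa_report>", nrow(x$metadata), "subjects;",
      nrow(x$stats), "analyses\n")
  print(x$stats)
  invisible(x)
}
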