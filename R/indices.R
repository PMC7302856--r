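main_conditions <- c("hands", "cosmetic_prosthesis", "active_prosthesis", "tools")

check_main_conditions <- function(x) {
  missing <- setdiff(main_conditions, rownames(x))
  if (length(missing)) {
    stop("RDM is missing condition(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Hand-similarity and prosthesis-similarity indices
#'
#' Two linear contrasts of an individual's pairwise condition distances, each
#' signed so that positive values support its hypothesis.
#'
#' The hand-similarity index tests visual embodiment (prostheses represented
#' like hands rather than tools):
#' \deqn{(Tools \leftrightarrow CosmP + Tools \leftrightarrow ActP) -
#'       (Hands \leftrightarrow CosmP + Hands \leftrightarrow ActP)}
#' It is the exact negative of the analogous tool-similarity contrast, so
#' significantly negative values indicate tool-like representation.
#'
#' The prosthesis-similarity index tests categorisation (the two prosthesis
#' types clustering together, away from their natural categories):
#' \deqn{3(Hands \leftrightarrow CosmP + Tools \leftrightarrow ActP) -
#'       2(Hands \leftrightarrow ActP + Tools \leftrightarrow CosmP +
#'         ActP \leftrightarrow CosmP)}
#' Distances expected to grow with categorisation are weighted positively and
#' those expected to shrink negatively; the weights balance so that any
#' equal-distance RDM scores zero on both indices.
#'
#' @param x An [rdm()] containing conditions `hands`, `cosmetic_prosthesis`,
#'   `active_prosthesis`, `tools`.
#' @return Scalar index value.
#' @export
hand_similarity_index <- function(x) {
  check_main_conditions(x)
  (rdm_entry(x, "tools", "cosmetic_prosthesis") +
     rdm_entry(x, "tools", "active_prosthesis")) -
    (rdm_entry(x, "hands", "cosmetic_prosthesis") +
       rdm_entry(x, "hands", "active_prosthesis"))
}

#' @rdname hand_similarity_index
#' @export
prosthesis_similarity_index <- function(x) {
  check_main_conditions(x)
  3 * (rdm_entry(x, "hands", "cosmetic_prosthesis") +
         rdm_entry(x, "tools", "active_prosthesis")) -
    2 * (rdm_entry(x, "hands", "active_prosthesis") +
           rdm_entry(x, "tools", "cosmetic_prosthesis") +
           rdm_entry(x, "active_prosthesis", "cosmetic_prosthesis"))
}

#' @rdname hand_similarity_index
#' @export
hand_tool_distance <- function(x) {
  check_main_conditions(x)
  rdm_entry(x, "hands", "tools")
}

#' Residualise indices on the hands-tools distance
#'
#' Controls for inter-individual differences in overall distance scale by
#' regressing each raw index on the subject's hands-tools distance (ordinary
#' least squares with intercept, fitted across the pooled cohort) and keeping
#' the residuals. Residuals sum to zero and are uncorrelated with the
#' covariate. If the covariate is constant the regression is undefined and
#' the function falls back to mean-centering, with a warning.
#'
#' @param raw Numeric vector of per-subject raw index values.
#' @param covariate Numeric vector of per-subject hands-tools distances.
#' @return Numeric vector of residualised index values.
#' @export
standardize_by_hand_tool <- function(raw, covariate) {
  stopifnot(length(raw) == length(covariate))
  if (length(raw) < 3) {
    stop("residualisation needs at least 3 subjects", call. = FALSE)
  }
  if (stats::var(covariate) == 0) {
    warning("constant hands-tools covariate; falling back to mean-centering",
            call. = FALSE)
    return(raw - mean(raw))
  }
  stats::resid(stats::lm(raw ~ covariate))
}

#' Per-subject similarity index table
#'
#' Tidy layer over the index computations: one row per subject with raw
#' indices, the hands-tools covariate, and residualised (standardised)
#' indices fitted either across the pooled cohort (default, so group
#' differences share one baseline) or within group.
#'
#' @param rdms Named list of per-subject [rdm()]s.
#' @param metadata Tibble with `subject_id` (matching `names(rdms)`) and
#'   `group`; extra columns are carried through.
#' @param pooling `"pooled"` or `"by_group"` residualisation.
#' @return Tibble with columns `subject_id`, `group`,
#'   `hand_similarity_raw`, `prosthesis_similarity_raw`,
#'   `hand_tool_distance`, `hand_similarity_std`,
#'   `prosthesis_similarity_std`, plus the remaining metadata columns.
#' @export
compute_similarity_indices <- function(rdms, metadata,
                                       pooling = c("pooled", "by_group")) {
  pooling <- match.arg(pooling)
  stopifnot(!is.null(names(rdms)), all(names(rdms) %in% metadata$subject_id))
  idx <- tibble::tibble(
    subject_id = names(rdms),
    hand_similarity_raw = purrr::map_dbl(rdms, hand_similarity_index),
    prosthesis_similarity_raw = purrr::map_dbl(rdms, prosthesis_similarity_index),
    hand_tool_distance = purrr::map_dbl(rdms, hand_tool_distance)
  )
  out <- dplyr::inner_join(idx, metadata, by = "subject_id")
  std <- function(df) {
    df$hand_similarity_std <-
      standardize_by_hand_tool(df$hand_similarity_raw, df$hand_tool_distance)
    df$prosthesis_similarity_std <-
      standardize_by_hand_tool(df$prosthesis_similarity_raw, df$hand_tool_distance)
    df
  }
  if (pooling == "pooled") {
    out <- std(out)
  } else {
    out <- out |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ std(.x)) |>
      dplyr::ungroup()
  }
  dplyr::relocate(out, "subject_id", "group", "hand_similarity_raw",
                  "prosthesis_similarity_raw", "hand_tool_distance",
                  "hand_similarity_std", "prosthesis_similarity_std")
}

#' Replace active-prosthesis distances for affected subjects
#'
#' Handles the subset of users who viewed a visually different exemplar in
#' the active-prosthesis condition: for each affected subject, the three
#' distances involving the active prosthesis (`tools-active`, `hands-active`,
#' `active-cosmetic`) are replaced by the mean of those distances over the
#' unaffected users. All other entries are untouched. The alternative
#' variant excludes the affected subjects entirely.
#'
#' @param rdms Named list of per-user [rdm()]s.
#' @param affected Character vector of affected subject ids (strict subset).
#' @param variant `"replace"` (default) or `"exclude"`.
#' @return Named list of RDMs (shorter under `"exclude"`).
#' @export
replace_active_distances <- function(rdms, affected,
                                     variant = c("replace", "exclude")) {
  variant <- match.arg(variant)
  stopifnot(!is.null(names(rdms)))
  affected <- intersect(affected, names(rdms))
  if (length(affected) == 0) return(rdms)
  if (length(affected) >= length(rdms)) {
    stop("all users affected: no reference group to take means from",
         call. = FALSE)
  }
  if (variant == "exclude") {
    return(rdms[setdiff(names(rdms), affected)])
  }
  rest <- rdms[setdiff(names(rdms), affected)]
  pairs <- list(c("tools", "active_prosthesis"),
                c("hands", "active_prosthesis"),
                c("active_prosthesis", "cosmetic_prosthesis"))
  means <- vapply(pairs, function(p) {
    mean(vapply(rest, rdm_entry, numeric(1), p[1], p[2]))
  }, numeric(1))
  for (id in affected) {
    m <- unclass(rdms[[id]])
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      m[p[1], p[2]] <- m[p[2], p[1]] <- means[k]
    }
    rdms[[id]] <- rdm(m, rownames(m))
  }
  rdms
}

#' Own-prosthesis distances normalised to the control baseline
#'
#' For a user whose RDM contains an `own_prosthesis` condition, the
#' own-to-hands and own-to-tools distances are each divided by the control
#' group's mean distance between the matched generic prosthesis condition and
#' hands/tools respectively. A value of 1 means the user's own prosthesis
#' sits exactly at the control baseline; values above 1 mean it is
#' represented more dissimilarly than controls represent a similar-looking
#' prosthesis.
#'
#' Matching rules: under `"type"`, a cosmetic own prosthesis is matched with
#' the controls' generic cosmetic condition and an active (mechanical or
#' myoelectric) own prosthesis with the generic active condition. Under
#' `"hand_likeness"`, active own prostheses flagged as visually hand-like are
#' re-matched with the controls' cosmetic condition instead.
#'
#' @param user_rdm [rdm()] containing `own_prosthesis`.
#' @param control_rdms List of control [rdm()]s.
#' @param own_type `"cosmetic"`, `"mechanical"`, or `"myoelectric"`.
#' @param hand_like Logical; used by the `"hand_likeness"` rule.
#' @param matching Matching rule.
#' @return Tibble with one row: `own_hand_normalized`, `own_tool_normalized`,
#'   `matched_control_condition`, `hand_like_flag`.
#' @export
own_prosthesis_normalized <- function(user_rdm, control_rdms,
                                      own_type,
                                      hand_like = FALSE,
                                      matching = c("type", "hand_likeness")) {
  matching <- match.arg(matching)
  stopifnot(inherits(user_rdm, "rdm"))
  if (!"own_prosthesis" %in% rownames(user_rdm)) {
    stop("user RDM has no own_prosthesis condition", call. = FALSE)
  }
  own_type <- match.arg(own_type, c("cosmetic", "mechanical", "myoelectric"))
  matched <- if (own_type == "cosmetic") {
    "cosmetic_prosthesis"
  } else if (matching == "hand_likeness" && isTRUE(hand_like)) {
    "cosmetic_prosthesis"
  } else {
    "active_prosthesis"
  }
  ctrl_hand <- mean(vapply(control_rdms, rdm_entry, numeric(1),
                           matched, "hands"))
  ctrl_tool <- mean(vapply(control_rdms, rdm_entry, numeric(1),
                           matched, "tools"))
  if (ctrl_hand == 0 || ctrl_tool == 0) {
    stop("control mean matched distance is zero; normalisation undefined",
         call. = FALSE)
  }
  tibble::tibble(
    own_hand_normalized = rdm_entry(user_rdm, "own_prosthesis", "hands") / ctrl_hand,
    own_tool_normalized = rdm_entry(user_rdm, "own_prosthesis", "tools") / ctrl_tool,
    matched_control_condition = matched,
    hand_like_flag = isTRUE(hand_like)
  )
}

#' Cohort-level own-prosthesis scores
#'
#' Applies [own_prosthesis_normalized()] to every user whose RDM contains the
#' own-prosthesis condition; users without it (e.g., those shown a placeholder
#' object) are excluded.
#'
#' @param user_rdms Named list of user [rdm()]s.
#' @param control_rdms List of control [rdm()]s.
#' @param metadata Tibble with `subject_id`, `own_condition`
#'   (cosmetic/mechanical/myoelectric or NA), and `own_hand_like` (0/1).
#' @param matching Matching rule, see [own_prosthesis_normalized()].
#' @return Tibble, one row per scored user.
#' @export
own_prosthesis_scores <- function(user_rdms, control_rdms, metadata,
                                  matching = c("type", "hand_likeness")) {
  matching <- match.arg(matching)
  rows <- purrr::imap(user_rdms, function(r, id) {
    meta <- metadata[metadata$subject_id == id, ]
    if (nrow(meta) != 1 || is.na(meta$own_condition) ||
        !"own_prosthesis" %in% rownames(r)) {
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(subject_id = id),
      own_prosthesis_normalized(r, control_rdms,
                                own_type = meta$own_condition,
                                hand_like = isTRUE(meta$own_hand_like == 1),
                                matching = matching)
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}
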