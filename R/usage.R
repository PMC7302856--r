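#' Prosthesis activity log (PAL) score
#'
#' The activity log asks how frequently the prosthesis is incorporated in an
#' inventory of 27 daily activities, each rated 0 (never), 1 (sometimes), or
#' 2 (very often). The score is the item sum divided by the maximum possible
#' sum (27 x 2 = 54), giving a scale from 0 to 1.
#'
#' @param items Numeric vector of exactly 27 ratings in `{0, 1, 2}`.
#' @return Scalar in `[0, 1]`.
#' @export
pal_score <- function(items) {
  if (length(items) != 27) {
    stop("PAL has exactly 27 items (got ", length(items), ")", call. = FALSE)
  }
  if (anyNA(items) || !all(items %in% 0:2)) {
    stop("PAL items must each be 0, 1, or 2", call. = FALSE)
  }
  sum(items) / 54
}

#' Wear frequency across prosthesis types
#'
#' Wear time is rated per prosthesis type on a 0-5 scale (0 = never,
#' 5 = daily > 8 h). For users of more than one prosthesis the rating of the
#' most frequently used one is taken, i.e., the maximum across types.
#'
#' @param wear_by_type Numeric vector (optionally named by type) of ratings
#'   in `{0, ..., 5}`.
#' @return Scalar rating.
#' @export
wear_frequency <- function(wear_by_type) {
  if (anyNA(wear_by_type) || !all(wear_by_type %in% 0:5)) {
    stop("wear ratings must each be in 0..5", call. = FALSE)
  }
  max(wear_by_type)
}

# Population (divisor n) z-score: the convention that reproduces the printed
# composite usage scores; sample-SD z-scores do not.
z_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero variance: z-score undefined", call. = FALSE)
  (x - mean(x)) / s
}

#' Composite prosthesis usage score
#'
#' Wear frequency and PAL are each z-transformed across the cohort (population
#' convention, divisor n) and summed. The score therefore has cohort mean
#' exactly zero and is invariant to affine rescaling of either input.
#'
#' @param pal Numeric vector of per-user PAL scores.
#' @param wear Numeric vector of per-user wear frequencies.
#' @return Numeric vector of usage scores (same order).
#' @export
usage_score <- function(pal, wear) {
  stopifnot(length(pal) == length(wear))
  if (length(pal) < 2) stop("usage_score needs a cohort of >= 2", call. = FALSE)
  z_pop(pal) + z_pop(wear)
}

#' Primary prosthesis classification
#'
#' The user's primary prosthesis is the type with the highest wear rating:
#' all-zero ratings give `non_user`, a unique maximum gives that type, and a
#' tied non-zero maximum across two or more types gives `hybrid`.
#'
#' @param wear_by_type Named numeric vector of wear ratings per type.
#' @return One of the type names, `"hybrid"`, or `"non_user"`.
#' @export
classify_primary <- function(wear_by_type) {
  if (anyNA(wear_by_type) || !all(wear_by_type %in% 0:5)) {
    stop("wear ratings must each be in 0..5", call. = FALSE)
  }
  if (all(wear_by_type == 0)) return("non_user")
  top <- which(wear_by_type == max(wear_by_type))
  if (length(top) > 1) return("hybrid")
  nm <- names(wear_by_type)
  if (is.null(nm)) nm <- paste0("type", seq_along(wear_by_type))
  nm[top]
}

#' Packaged usage-table fixture
#'
#' A transcription of the prosthesis users' demographics and usage table
#' (32 users: gender, age, amputation details, PAL score, wear rating per
#' prosthesis type, the printed composite usage score, and the own-prosthesis
#' condition fields), shipped for regression tests of the usage chain.
#'
#' @return Tibble with one row per user.
#' @export
usage_table_fixture <- function() {
  path <- system.file("extdata", "usage_table.csv", package = "prosrsa",
                      mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  tibble::as_tibble(tbl)
}

#' Recompute the derived usage columns of a metadata table
#'
#' Applies the full usage chain (wear frequency, composite usage score with
#' population z-scores, primary-type classification) to a table holding
#' `pal` and `wear_cosmetic`/`wear_mechanical`/`wear_myoelectric` columns,
#' and, when a printed `usage_score_printed` column is present, diffs the
#' recomputed scores against it at 2 decimals.
#'
#' @param data Tibble; defaults to the packaged fixture
#'   ([usage_table_fixture()]).
#' @return The table with added columns `wear_frequency`, `usage_score`,
#'   `primary_class`, and (if printed scores exist) `usage_score_match`.
#' @export
reproduce_usage_table <- function(data = usage_table_fixture()) {
  if (nrow(data) == 0) stop("empty table", call. = FALSE)
  need <- c("pal", "wear_cosmetic", "wear_mechanical", "wear_myoelectric")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  wear <- as.matrix(data[, c("wear_cosmetic", "wear_mechanical",
                             "wear_myoelectric")])
  colnames(wear) <- c("cosmetic", "mechanical", "myoelectric")
  data$wear_frequency <- apply(wear, 1, wear_frequency)
  data$usage_score <- usage_score(data$pal, data$wear_frequency)
  data$primary_class <- apply(wear, 1, classify_primary)
  if ("usage_score_printed" %in% names(data)) {
    data$usage_score_match <-
      round(data$usage_score, 2) == data$usage_score_printed
  }
  data
}

#' Prosthesis-type subgroups for the by-type analysis
#'
#' Splits users into primary cosmetic versus primary active (mechanical or
#' myoelectric) users for the analyses comparing prosthesis types. Non-users
#' are always excluded, as are any subjects named in `exclude` (e.g., those
#' shown a visually different active exemplar). The single-hybrid case is
#' grouped with active users by default, which reproduces the reported
#' subgroup sizes; set `hybrid = "exclude"` to drop hybrids instead.
#'
#' @param data Table with `primary_class` (and `subject_id` if `exclude` is
#'   used).
#' @param exclude Character vector of subject ids to drop.
#' @param hybrid `"active"` (default) or `"exclude"`.
#' @return The table filtered to analysed users, with a `type_group` column
#'   (`"cosmetic"` / `"active"`).
#' @export
by_type_subgroups <- function(data, exclude = character(),
                              hybrid = c("active", "exclude")) {
  hybrid <- match.arg(hybrid)
  out <- dplyr::filter(data, .data$primary_class != "non_user")
  if (length(exclude)) {
    out <- dplyr::filter(out, !.data$subject_id %in% exclude)
  }
  if (hybrid == "exclude") {
    out <- dplyr::filter(out, .data$primary_class != "hybrid")
  }
  dplyr::mutate(out, type_group = dplyr::if_else(
    .data$primary_class == "cosmetic", "cosmetic", "active"))
}
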