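#' Representational geometry templates
#'
#' A geometry template describes the "true" representational structure planted
#' in a synthetic cohort: an ordered set of condition labels and a target
#' representational dissimilarity matrix (RDM) of desired squared pattern
#' distances between the condition means, in arbitrary units. The
#' `usage_coupling` scalar controls how strongly a prosthesis user's geometry
#' is displaced from the control template towards the prosthesis-cluster
#' template per unit of (min-max standardised) usage score.
#'
#' @param condition_names Character vector of unique condition labels.
#' @param target_rdm Symmetric numeric matrix with zero diagonal and
#'   non-negative entries; `target_rdm[i, j]` is the desired squared Euclidean
#'   distance between the mean patterns of conditions `i` and `j`.
#' @param usage_coupling Scalar in `[0, 1]`: displacement towards the user
#'   template per unit standardised usage.
#'
#' @return An object of class `geometry_template`.
#' @seealso [default_control_template()], [default_user_template()],
#'   [embed_geometry()]
#' @export
geometry_template <- function(condition_names, target_rdm, usage_coupling = 1) {
  condition_names <- as.character(condition_names)
  if (anyDuplicated(condition_names)) {
    stop("condition_names must be unique", call. = FALSE)
  }
  target_rdm <- as.matrix(target_rdm)
  n <- length(condition_names)
  if (!all(dim(target_rdm) == n)) {
    stop("target_rdm must be ", n, " x ", n, call. = FALSE)
  }
  if (!all(is.finite(target_rdm))) stop("target_rdm must be finite", call. = FALSE)
  if (max(abs(target_rdm - t(target_rdm))) > 1e-10) {
    stop("target_rdm must be symmetric", call. = FALSE)
  }
  if (any(diag(target_rdm) != 0)) {
    stop("target_rdm must have a zero diagonal", call. = FALSE)
  }
  if (any(target_rdm < 0)) stop("target_rdm entries must be non-negative", call. = FALSE)
  if (!is.finite(usage_coupling)) stop("usage_coupling must be finite", call. = FALSE)
  dimnames(target_rdm) <- list(condition_names, condition_names)
  structure(
    list(
      condition_names = condition_names,
      target_rdm = target_rdm,
      usage_coupling = usage_coupling
    ),
    class = "geometry_template"
  )
}

#' @export
print.geometry_template <- function(x, ...) {
  cat("<geometry_template>", length(x$condition_names), "conditions:",
      paste(x$condition_names, collapse = ", "), "\n")
  cat("usage_coupling:", x$usage_coupling, "\n")
  print(round(x$target_rdm, 3))
  invisible(x)
}

# Planar coordinates used by both default templates. Conditions sit on a
# hand--tool axis (x) with prostheses offset on y; squared distances between
# these rows define embeddable target RDMs by construction.
template_coords <- function(kind = c("control", "user")) {
  kind <- match.arg(kind)
  if (kind == "control") {
    # cosmetic next to hands, active next to tools: the "natural category"
    # geometry seen in two-handed controls
    rbind(
      hands               = c(0, 0),
      cosmetic_prosthesis = c(0, 1),
      active_prosthesis   = c(2, 1),
      tools               = c(2, 0)
    )
  } else {
    # the two prostheses clustered together, away from both hands and tools
    rbind(
      hands               = c(0,    0),
      cosmetic_prosthesis = c(0.75, 1.5),
      active_prosthesis   = c(1.25, 1.5),
      tools               = c(2,    0)
    )
  }
}

coords_to_rdm <- function(coords) {
  d <- as.matrix(stats::dist(coords))^2
  dimnames(d) <- list(rownames(coords), rownames(coords))
  d
}

#' Default planted geometries
#'
#' `default_control_template()` encodes the natural-category geometry expected
#' in two-handed controls: cosmetic prostheses close to hands, active
#' prostheses close to tools, prosthesis types far apart.
#' `default_user_template()` encodes the prosthesis-cluster geometry expected
#' in experienced prosthesis users: the two prosthesis types close together
#' and displaced from both hands and tools, with the hands-tools distance
#' unchanged. Units are arbitrary squared-distance units; both templates share
#' the same condition order and total hands-tools separation so that the two
#' geometries differ in structure, not overall scale.
#'
#' @param usage_coupling Scalar in `[0, 1]` passed to [geometry_template()].
#' @return A `geometry_template`.
#' @export
default_control_template <- function(usage_coupling = 1) {
  geometry_template(
    rownames(template_coords("control")),
    coords_to_rdm(template_coords("control")),
    usage_coupling = usage_coupling
  )
}

#' @rdname default_control_template
#' @export
default_user_template <- function(usage_coupling = 1) {
  geometry_template(
    rownames(template_coords("user")),
    coords_to_rdm(template_coords("user")),
    usage_coupling = usage_coupling
  )
}

#' Embed a target RDM as condition-mean voxel patterns
#'
#' Realises a geometry template as a `conditions x voxels` matrix of true mean
#' patterns whose pairwise squared Euclidean distances reproduce the target
#' RDM. The embedding is obtained by classical multidimensional scaling of the
#' doubly-centred Gram matrix; if the target is not exactly embeddable (the
#' Gram matrix has negative eigenvalues beyond numerical noise) it is
#' projected to the nearest embeddable matrix by clipping those eigenvalues,
#' with a warning. A random orthonormal rotation spreads the low-dimensional
#' coordinates across voxels so that no individual voxel axis carries
#' structure.
#'
#' @param template A [geometry_template()].
#' @param n_voxels Number of voxels (columns); must be at least the embedding
#'   dimension (number of conditions minus one).
#' @param seed Integer seed for the random rotation.
#' @return Numeric matrix `length(condition_names) x n_voxels` with condition
#'   row names.
#' @export
embed_geometry <- function(template, n_voxels, seed = 1L) {
  stopifnot(inherits(template, "geometry_template"))
  d <- template$target_rdm
  n <- nrow(d)
  if (n_voxels < n - 1) {
    stop("n_voxels must be at least ", n - 1, " to embed ", n, " conditions",
         call. = FALSE)
  }
  # classical MDS: B = -1/2 J D J
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% d %*% j
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  ev <- eig$values
  tol <- 1e-8 * max(abs(ev), 1)
  if (any(ev < -tol)) {
    warning("target_rdm is not squared-Euclidean embeddable; ",
            "projecting to the nearest embeddable matrix ",
            "(clipping negative Gram eigenvalues)", call. = FALSE)
  }
  ev <- pmax(ev, 0)
  k <- max(1L, sum(ev > tol))
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  withr::with_seed(seed, {
    g <- matrix(stats::rnorm(n_voxels * k), n_voxels, k)
    q <- qr.Q(qr(g)) # n_voxels x k orthonormal basis
    out <- coords %*% t(q)
  })
  rownames(out) <- template$condition_names
  out
}
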