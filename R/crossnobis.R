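#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric `conditions x conditions` matrix of cross-validated
#' distances with a zero diagonal. Because the crossnobis estimator is
#' cross-validated it is unbiased, and individual entries can legitimately be
#' negative.
#'
#' @param distances Symmetric numeric matrix, zero diagonal, finite entries.
#' @param condition_names Optional condition labels (defaults to the matrix
#'   dimnames).
#' @return An object of class `rdm`.
#' @export
rdm <- function(distances, condition_names = rownames(distances)) {
  distances <- as.matrix(distances)
  if (is.null(condition_names)) {
    condition_names <- paste0("cond", seq_len(nrow(distances)))
  }
  stopifnot(nrow(distances) == ncol(distances),
            length(condition_names) == nrow(distances))
  if (!all(is.finite(distances))) stop("distances must be finite", call. = FALSE)
  if (max(abs(distances - t(distances))) > 1e-10) {
    stop("distances must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(distances)) > 1e-12)) {
    stop("distances must have a zero diagonal", call. = FALSE)
  }
  diag(distances) <- 0
  dimnames(distances) <- list(condition_names, condition_names)
  structure(distances, class = c("rdm", "matrix"))
}

#' @export
print.rdm <- function(x, ...) {
  cat("<rdm>", nrow(x), "conditions (crossnobis units)\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Look up one pairwise distance
#'
#' @param x An `rdm`.
#' @param a,b Condition names.
#' @return Scalar distance.
#' @export
rdm_entry <- function(x, a, b) {
  stopifnot(inherits(x, "rdm"))
  missing <- setdiff(c(a, b), rownames(x))
  if (length(missing)) {
    stop("condition(s) missing from RDM: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unname(unclass(x)[a, b])
}

#' Long-format view of an RDM
#'
#' @param x An `rdm`.
#' @param ... Unused.
#' @return Tibble with columns `condition_a`, `condition_b`, `distance`, one
#'   row per unordered condition pair.
#' @export
tidy.rdm <- function(x, ...) {
  cn <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    condition_a = cn[idx[, 1]],
    condition_b = cn[idx[, 2]],
    distance = unclass(x)[idx]
  )
}

#' Average a list of RDMs entrywise
#'
#' Used for the group-mean RDM that dendrograms are built on. All RDMs must
#' share conditions; conditions are aligned by name.
#'
#' @param rdms List of `rdm` objects.
#' @return An `rdm`.
#' @export
mean_rdm <- function(rdms) {
  stopifnot(length(rdms) >= 1)
  cn <- rownames(rdms[[1]])
  acc <- Reduce(`+`, lapply(rdms, function(r) {
    stopifnot(inherits(r, "rdm"))
    if (!setequal(rownames(r), cn)) {
      stop("RDMs disagree in conditions", call. = FALSE)
    }
    unclass(r)[cn, cn]
  }))
  rdm(acc / length(rdms), cn)
}

#' Cross-validated Mahalanobis (crossnobis/LDC) RDM
#'
#' For every pair of conditions, the leave-one-run-out linear discriminant
#' contrast: each fold holds out one run, the pattern difference is averaged
#' over the training runs and paired with the held-out run's difference, and
#' the fold value is their inner product divided by the voxel count. The
#' distance is the mean over folds. Because training and test differences
#' carry independent noise the estimator is unbiased: its expectation is zero
#' for identical true patterns, and single estimates may be negative. Patterns
#' should already be prewhitened (see [prewhiten()]) for distances in
#' Mahalanobis units.
#'
#' @param whitened_betas Array `runs x conditions x voxels` (condition
#'   dimnames become the RDM labels). At least 2 runs; every condition must
#'   be present (non-NA) in every run.
#' @return An [rdm()].
#' @export
crossnobis_rdm <- function(whitened_betas) {
  stopifnot(is.array(whitened_betas), length(dim(whitened_betas)) == 3)
  n_runs <- dim(whitened_betas)[1]
  n_cond <- dim(whitened_betas)[2]
  n_vox <- dim(whitened_betas)[3]
  if (n_runs < 2) {
    stop("crossnobis needs at least 2 runs", call. = FALSE)
  }
  if (anyNA(whitened_betas)) {
    bad <- which(apply(whitened_betas, c(1, 2), anyNA), arr.ind = TRUE)
    stop("condition '", dimnames(whitened_betas)[[2]][bad[1, 2]],
         "' is missing in run ", bad[1, 1], call. = FALSE)
  }
  cn <- dimnames(whitened_betas)[[2]]
  if (is.null(cn)) cn <- paste0("cond", seq_len(n_cond))
  d <- matrix(0, n_cond, n_cond)
  for (a in seq_len(n_cond - 1)) {
    for (b in (a + 1):n_cond) {
      # runs x voxels matrix of per-run pattern differences
      delta <- whitened_betas[, a, , drop = FALSE] -
        whitened_betas[, b, , drop = FALSE]
      delta <- matrix(delta, n_runs, n_vox)
      folds <- vapply(seq_len(n_runs), function(f) {
        train <- colMeans(delta[-f, , drop = FALSE])
        sum(train * delta[f, ]) / n_vox
      }, numeric(1))
      d[a, b] <- d[b, a] <- mean(folds)
    }
  }
  rdm(d, cn)
}

#' Linkage dendrogram of a group-mean RDM
#'
#' Agglomerative clustering of the conditions under the given linkage
#' (average/UPGMA by default), used to visualise the representational
#' structure. Negative cross-validated distances are clipped to zero for tree
#' construction only, with a warning.
#'
#' @param x An `rdm` (typically a group mean, see [mean_rdm()]).
#' @param method Linkage method passed to [stats::hclust()].
#' @return A `prosrsa_dendrogram`: list with the `hclust` object, the merge
#'   order as a list of label sets, merge `heights`, and a `newick` string.
#' @export
linkage_dendrogram <- function(x, method = "average") {
  stopifnot(inherits(x, "rdm"))
  m <- unclass(x)
  if (any(m < 0)) {
    warning("negative distances clipped to 0 for dendrogram construction",
            call. = FALSE)
    m[m < 0] <- 0
  }
  hc <- stats::hclust(stats::as.dist(m), method = method)
  merges <- lapply(seq_len(nrow(hc$merge)), function(i) {
    sort(hc$labels[cluster_members(hc$merge, i)])
  })
  structure(
    list(hclust = hc, merges = merges, heights = hc$height,
         newick = ape::write.tree(ape::as.phylo(hc))),
    class = "prosrsa_dendrogram"
  )
}

# Leaves belonging to merge step i of an hclust merge matrix.
cluster_members <- function(merge, i) {
  row <- merge[i, ]
  unlist(lapply(row, function(k) {
    if (k < 0) -k else cluster_members(merge, k)
  }))
}

#' @export
print.prosrsa_dendrogram <- function(x, ...) {
  cat("<prosrsa_dendrogram>\n")
  for (i in seq_along(x$merges)) {
    cat(sprintf("  merge %d at %.4g: {%s}\n", i, x$heights[i],
                paste(x$merges[[i]], collapse = ", ")))
  }
  invisible(x)
}
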