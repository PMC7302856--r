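#' Select the top localizer voxels per hemisphere
#'
#' Defines a subject-specific region of interest by picking, within an
#' anatomical mask and separately for each hemisphere, the `n_per_hemisphere`
#' voxels with the largest localizer statistic (e.g., the headless bodies >
#' objects contrast). Both hemispheres are then treated as a single ROI. Ties
#' at the cutoff are broken by ascending voxel index, so selection is
#' deterministic and invariant to any strictly monotone transform of the
#' statistic map.
#'
#' @param statmap Numeric vector, one statistic per candidate voxel.
#' @param hemisphere Character vector of per-voxel hemisphere labels.
#' @param mask Logical vector; voxels outside the mask are never selected.
#'   Default: all voxels eligible.
#' @param n_per_hemisphere Voxels to keep per hemisphere (default 250). Use
#'   `NULL` to keep every masked voxel (whole-mask anatomical ROI variant).
#' @return A tibble of class `roi_definition` with columns `voxel`
#'   (index into the candidate set), `hemisphere`, and `statistic`, ordered by
#'   hemisphere then descending statistic.
#' @export
select_top_voxels <- function(statmap, hemisphere, mask = NULL,
                              n_per_hemisphere = 250) {
  n <- length(statmap)
  stopifnot(length(hemisphere) == n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  hemis <- unique(hemisphere)
  rows <- lapply(hemis, function(h) {
    idx <- which(mask & hemisphere == h)
    if (is.null(n_per_hemisphere)) {
      keep <- idx[order(-statmap[idx], idx)]
    } else {
      if (length(idx) < n_per_hemisphere) {
        stop("hemisphere '", h, "' has only ", length(idx),
             " masked voxels; ", n_per_hemisphere, " requested (short by ",
             n_per_hemisphere - length(idx), ")", call. = FALSE)
      }
      # stable: descending statistic, ascending index among ties
      keep <- idx[order(-statmap[idx], idx)][seq_len(n_per_hemisphere)]
    }
    tibble::tibble(voxel = keep, hemisphere = h, statistic = statmap[keep])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("roi_definition", class(out))
  out
}

#' Mean ROI activity per condition
#'
#' The univariate check run before any multivariate analysis: for each
#' condition, the parameter estimate averaged across all runs and all ROI
#' voxels.
#'
#' @param betas Array `runs x conditions x voxels` of beta estimates over the
#'   candidate voxel set.
#' @param roi A [select_top_voxels()] result (or any data frame with a
#'   `voxel` column).
#' @return Tibble with columns `condition` and `mean_beta`.
#' @export
mean_roi_activity <- function(betas, roi) {
  stopifnot(is.array(betas), length(dim(betas)) == 3)
  vox <- roi$voxel
  if (length(vox) == 0) stop("empty ROI", call. = FALSE)
  if (max(vox) > dim(betas)[3]) {
    stop("ROI voxel indices exceed the beta array", call. = FALSE)
  }
  conds <- dimnames(betas)[[2]]
  if (is.null(conds)) conds <- paste0("cond", seq_len(dim(betas)[2]))
  m <- apply(betas[, , vox, drop = FALSE], 2, mean)
  tibble::tibble(condition = conds, mean_beta = unname(m))
}

#' Restrict beta patterns and residuals to an ROI
#'
#' @param subject A `synthetic_subject` (or any list with `betas` and
#'   `residuals` in the same layout).
#' @param roi A [select_top_voxels()] result.
#' @return The subject with `betas` and `residuals` subset to the ROI voxels,
#'   in ROI order.
#' @export
subset_to_roi <- function(subject, roi) {
  vox <- roi$voxel
  subject$betas <- subject$betas[, , vox, drop = FALSE]
  subject$residuals <- lapply(subject$residuals,
                              function(r) r[, vox, drop = FALSE])
  subject
}

#' Read an ROI triplet from NIfTI volumes
#'
#' Optional ingestion path for real data: a statistic volume, a mask volume
#' (non-zero = inside), and a hemisphere label volume (1 = left, 2 = right)
#' on the same grid are flattened into the vectors [select_top_voxels()]
#' expects. Requires the RNifti package.
#'
#' @param stat_file,mask_file,hemisphere_file Paths to NIfTI volumes.
#' @return A list with `statmap`, `mask`, `hemisphere` vectors over the
#'   masked-grid candidate voxels and `grid_index`, their linear index into
#'   the volume.
#' @export
read_roi_volumes <- function(stat_file, mask_file, hemisphere_file) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required to read NIfTI volumes", call. = FALSE)
  }
  stat <- as.vector(RNifti::readNifti(stat_file))
  mask <- as.vector(RNifti::readNifti(mask_file)) != 0
  hemi <- as.vector(RNifti::readNifti(hemisphere_file))
  stopifnot(length(stat) == length(mask), length(stat) == length(hemi))
  keep <- which(mask & hemi %in% c(1, 2))
  list(
    statmap = stat[keep],
    mask = rep(TRUE, length(keep)),
    hemisphere = c("left", "right")[hemi[keep]],
    grid_index = keep
  )
}
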