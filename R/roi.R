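#' Read / write a table of spherical ROIs
#'
#' TSV with columns `roi_name`, `hemisphere`, `x`, `y`, `z` (MNI mm) and
#' `radius_mm`, mirroring the usual coordinate tables of regions of interest.
#'
#' @param path TSV file path.
#' @return A tibble of ROI specifications.
#' @export
read_roi_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("roi_name", "hemisphere", "x", "y", "z", "radius_mm")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop_socmap(paste0("ROI table lacks columns: ", paste(miss, collapse = ", ")),
                "validation")
  }
  if (any(tbl$radius_mm <= 0)) stop_socmap("radius_mm must be positive", "validation")
  tbl
}

#' @rdname read_roi_table
#' @param rois ROI tibble.
#' @export
write_roi_table <- function(rois, path) {
  readr::write_tsv(rois, path, progress = FALSE)
  invisible(path)
}

#' Spherical ROI voxel mask
#'
#' Selects the voxels whose world-space centers lie within `radius_mm` of
#' `center_mm` (closed ball, no partial-volume weighting). Voxel centers are
#' computed through the affine from 0-based indices.
#'
#' @param center_mm Length-3 world (MNI mm) center.
#' @param radius_mm Sphere radius in mm (> 0).
#' @param affine 4x4 voxel-to-world transform.
#' @param dim3 Spatial grid dimensions (length 3).
#' @return Logical 3D array marking in-sphere voxels.
#' @export
sphere_mask <- function(center_mm, radius_mm, affine, dim3) {
  if (radius_mm <= 0) stop_socmap("radius_mm must be positive", "validation")
  xyz <- voxel_centers_mm(affine, dim3)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  inside <- d2 <= radius_mm^2 + 1e-9
  if (!any(inside)) {
    stop_socmap("sphere contains no voxel centers", "empty_roi")
  }
  array(inside, dim = dim3)
}

#' Mean time series within a spherical ROI
#'
#' Per-volume mean of the series over the in-mask voxels of the sphere.
#'
#' @param series A [volume_series()].
#' @param center_mm,radius_mm Sphere center (MNI mm) and radius.
#' @return Numeric vector, one value per retained volume.
#' @export
mean_roi_timeseries <- function(series, center_mm, radius_mm) {
  sp <- dim(series$data)[1:3]
  ball <- sphere_mask(center_mm, radius_mm, series$affine, sp)
  idx <- which(ball & series$mask)
  if (length(idx) == 0) {
    stop_socmap("sphere lies entirely outside the brain mask", "empty_roi")
  }
  y <- series_matrix(series)
  rowMeans(y[, idx, drop = FALSE])
}

#' ROI-by-time matrix for a set of spheres
#'
#' @param series A [volume_series()].
#' @param rois ROI tibble (`roi_name`, `x`, `y`, `z`, `radius_mm`).
#' @param radius_mm Optional radius overriding the table (e.g. 6 mm spheres
#'   for connectivity).
#' @return Time x ROI matrix with ROI names as column names.
#' @export
roi_timeseries_matrix <- function(series, rois, radius_mm = NULL) {
  cols <- lapply(seq_len(nrow(rois)), function(i) {
    r <- if (!is.null(radius_mm)) radius_mm else rois$radius_mm[i]
    mean_roi_timeseries(series, c(rois$x[i], rois$y[i], rois$z[i]), r)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- rois$roi_name
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROI beta summary across subjects
#'
#' For each feature: the sphere-mean beta per subject, then the
#' across-subject mean with a t-based 95% confidence interval (error bars of
#' the mean beta weight across subjects).
#'
#' @param subject_betas List over subjects; each element a named list of
#'   per-feature beta [stat_map()]s.
#' @param center_mm Sphere center (MNI mm).
#' @param radius_mm Sphere radius (default 3 mm).
#' @param conf Confidence level (default 0.95).
#' @return Tibble (`feature`, `mean_beta`, `ci_lower`, `ci_upper`,
#'   `n_subjects`).
#' @export
beta_summary <- function(subject_betas, center_mm, radius_mm = 3, conf = 0.95) {
  if (length(subject_betas) < 2) {
    stop_socmap("beta summary needs at least 2 subjects", "validation")
  }
  feats <- names(subject_betas[[1]])
  for (sb in subject_betas) {
    miss <- setdiff(feats, names(sb))
    if (length(miss) > 0) {
      stop_socmap(paste0("missing feature maps: ", paste(miss, collapse = ", ")),
                  "completeness")
    }
  }
  ref <- subject_betas[[1]][[1]]
  ball <- sphere_mask(center_mm, radius_mm, ref$affine, dim(ref$values))
  purrr::map_dfr(feats, function(f) {
    per_subj <- vapply(subject_betas, function(sb) {
      idx <- which(ball & sb[[f]]$mask)
      if (length(idx) == 0) stop_socmap("sphere outside mask", "empty_roi")
      mean(sb[[f]]$values[idx])
    }, numeric(1))
    n <- length(per_subj)
    mu <- mean(per_subj)
    se <- sd(per_subj) / sqrt(n)
    half <- qt(1 - (1 - conf) / 2, df = n - 1) * se
    tibble::tibble(
      feature = f, mean_beta = mu,
      ci_lower = mu - half, ci_upper = mu + half, n_subjects = n
    )
  })
}

#' Locate overlap peaks
#'
#' Deterministic helper for picking ROI centers from a cumulative overlap
#' map: voxels are ranked by overlap count, ties broken by a mean-t map,
#' then by lexicographic index order; peaks closer than `min_separation_mm`
#' to an already selected peak are skipped.
#'
#' @param overlap An overlap [stat_map()].
#' @param t_mean A t [stat_map()] used for tie-breaking.
#' @param n_peaks Number of peaks to return.
#' @param min_separation_mm Minimum distance between peaks.
#' @return Tibble (`roi_name`, `x`, `y`, `z`, `overlap`, `t`).
#' @export
find_overlap_peaks <- function(overlap, t_mean, n_peaks = 1,
                               min_separation_mm = 12) {
  mask <- overlap$mask & t_mean$mask
  idx <- which(mask)
  ov <- overlap$values[idx]
  tv <- t_mean$values[idx]
  ord <- order(-ov, -tv, idx)
  xyz <- voxel_centers_mm(overlap$affine, dim(overlap$values))[idx, , drop = FALSE]
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) >= n_peaks) break
    if (length(picked) > 0) {
      d <- sqrt(rowSums((xyz[picked, , drop = FALSE] -
                           matrix(xyz[i, ], length(picked), 3, byrow = TRUE))^2))
      if (any(d < min_separation_mm)) next
    }
    picked <- c(picked, i)
  }
  tibble::tibble(
    roi_name = paste0("peak_", seq_along(picked)),
    x = xyz[picked, 1], y = xyz[picked, 2], z = xyz[picked, 3],
    overlap = ov[picked], t = tv[picked]
  )
}
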