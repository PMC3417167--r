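#' Simulate a full naturalistic-fMRI study
#'
#' Generates the whole synthetic study at the default design scale: two-rater
#' rating tracks for 137 clips, regressors on the TR grid (770 volumes, first
#' two discarded, so 768 analyzed), the first-level design, and per-subject
#' BOLD series with planted region effects and AR(1) noise. The concatenated
#' rating track is longer than the scan and is truncated at the acquisition
#' end.
#'
#' @param config A [run_config()].
#' @param n_subjects Number of subjects (default 19).
#' @param n_volumes_total Acquired volumes before discarding (default 770).
#' @param n_discard Initial volumes discarded (default 2).
#' @param shape,voxel_mm Grid geometry for the synthetic brain.
#' @param amplitude,noise_sd,ar1_rho,subject_sd Signal / noise parameters
#'   passed to [ground_truth_regions()] and [generate_bold()].
#' @param n_clips Number of clips.
#' @param seed Base seed for all randomness.
#' @return List: `rating_set`, `regressors`, `design` (non-orthogonalized),
#'   `design_orth`, `truth`, `series`, `subject_betas`, `config`.
#' @export
simulate_study <- function(config = run_config(), n_subjects = 19,
                           n_volumes_total = 770, n_discard = 2,
                           shape = c(24, 24, 24), voxel_mm = 4,
                           amplitude = 1, noise_sd = 2, ar1_rho = 0.4,
                           subject_sd = 0.25, n_clips = 137, seed = NULL) {
  nt <- n_volumes_total - n_discard
  rs <- generate_ratings(n_clips = n_clips, rate_hz = config$rating_rate_hz,
                         seed = child_seed(seed, 1))
  regressors <- ratings_to_regressors(rs, tr_s = config$tr_s, n_volumes = nt)
  design <- build_design_matrix(
    regressors, tr_s = config$tr_s,
    highpass_cutoff_s = config$highpass_cutoff_s,
    hrf_mode = config$hrf_mode, orthogonalize = FALSE
  )
  design_orth <- build_design_matrix(
    regressors, tr_s = config$tr_s,
    highpass_cutoff_s = config$highpass_cutoff_s,
    hrf_mode = config$hrf_mode, orthogonalize = TRUE,
    ortho_stage = config$ortho_stage
  )
  truth <- ground_truth_regions(shape = shape, voxel_mm = voxel_mm,
                                amplitude = amplitude)
  bold <- generate_bold(design, truth, n_subjects = n_subjects,
                        noise_sd = noise_sd, ar1_rho = ar1_rho,
                        subject_sd = subject_sd, tr_s = config$tr_s,
                        n_discarded = n_discard, seed = child_seed(seed, 2))
  list(
    rating_set = rs, regressors = regressors,
    design = design, design_orth = design_orth,
    truth = bold$truth, series = bold$series,
    subject_betas = bold$subject_betas, config = config
  )
}

#' First-level fits for every subject
#'
#' @param series List of [volume_series()].
#' @param design A design matrix.
#' @param mode `"combined"` or `"per_feature"` (see [fit_first_level()]).
#' @param statistics `"full"` or `"beta_only"`.
#' @return Named list of `first_level_fit`s.
#' @export
fit_all_subjects <- function(series, design, mode = "combined",
                             statistics = "full") {
  fits <- lapply(series, fit_first_level, design = design, mode = mode,
                 statistics = statistics)
  names(fits) <- vapply(series, `[[`, character(1), "subject_id")
  fits
}

#' Group-level feature maps with FDR thresholding
#'
#' Second-level one-sample t-test per feature over subjects' beta maps, then
#' voxelwise BH-FDR significance restricted to positive effects (cumulative
#' activation counts activation, not deactivation).
#'
#' @param fits List of `first_level_fit`s (one per subject).
#' @param q FDR level.
#' @param features Features to test (default: all in the fits).
#' @return Named list per feature: `group` (group_fit), `significance`,
#'   `p_star`, `n_significant`.
#' @export
group_feature_maps <- function(fits, q = 0.05, features = NULL) {
  if (is.null(features)) features <- fits[[1]]$features
  out <- lapply(features, function(f) {
    gf <- one_sample_t(lapply(fits, function(fit) fit$beta[[f]]))
    fdr <- fdr_significance(gf$p, q = q, t_map = gf$t, positive_only = TRUE)
    list(group = gf, significance = fdr$significance,
         p_star = fdr$p_star, n_significant = fdr$n_significant)
  })
  names(out) <- features
  out
}

#' End-to-end overlap analysis (original and orthogonalized)
#'
#' Runs the full mapping chain on a set of subjects for both analysis
#' strategies and returns the cumulative social-feature overlap maps. The
#' original (non-orthogonalized) strategy fits all 14 regressors in one GLM;
#' the orthogonalized strategy fits each mutually-residualized feature
#' regressor in its own GLM.
#'
#' @param series List of [volume_series()].
#' @param design Non-orthogonalized design.
#' @param design_orth Orthogonalized design.
#' @param config A [run_config()] (FDR level).
#' @param social Social feature names counted in the overlap map.
#' @return List: `overlap_original`, `overlap_orthogonalized` (stat maps),
#'   `group_original`, `group_orthogonalized`, `fits_original`,
#'   `fits_orthogonalized`.
#' @export
run_overlap_analysis <- function(series, design, design_orth,
                                 config = run_config(),
                                 social = social_features()) {
  dual <- lapply(series, fit_subject_dual, design = design,
                 design_orth = design_orth)
  names(dual) <- vapply(series, `[[`, character(1), "subject_id")
  fits_orig <- lapply(dual, `[[`, "original")
  fits_orth <- lapply(dual, `[[`, "orthogonalized")
  grp_orig <- group_feature_maps(fits_orig, q = config$fdr_q, features = social)
  grp_orth <- group_feature_maps(fits_orth, q = config$fdr_q, features = social)
  list(
    overlap_original = overlap_map(lapply(grp_orig, `[[`, "significance")),
    overlap_orthogonalized = overlap_map(lapply(grp_orth, `[[`, "significance")),
    group_original = grp_orig,
    group_orthogonalized = grp_orth,
    fits_original = fits_orig,
    fits_orthogonalized = fits_orth
  )
}

#' ROI connectivity and community structure
#'
#' Extracts mean sphere time series per ROI and subject, computes subject
#' correlation matrices, the Fisher-z group mean, the circular-shift
#' permutation threshold, the thresholded graph, and its map-equation
#' community partition.
#'
#' @param series List of [volume_series()].
#' @param rois ROI tibble (`roi_name`, `x`, `y`, `z`, ...).
#' @param config A [run_config()]; uses `roi_radius_conn_mm`,
#'   `n_permutations`, `min_shift_samples`, `n_community_restarts`.
#' @param n_perm Override for the permutation count (defaults to config).
#' @param seed RNG seed for permutations and restarts.
#' @return List: `roi_series`, `subject_r`, `mean_r`, `perm` (threshold
#'   object), `graph`, `partition`.
#' @export
run_connectivity_analysis <- function(series, rois, config = run_config(),
                                      n_perm = NULL, seed = NULL) {
  if (is.null(n_perm)) n_perm <- config$n_permutations
  roi_ts <- lapply(series, roi_timeseries_matrix, rois = rois,
                   radius_mm = config$roi_radius_conn_mm)
  subject_r <- lapply(roi_ts, subject_connectivity)
  mean_r <- group_mean_connectivity(subject_r)
  perm <- permutation_threshold(roi_ts, n_perm = n_perm,
                                min_shift = config$min_shift_samples,
                                seed = child_seed(seed, 1))
  graph <- build_graph(mean_r, perm$threshold, nodes = rois$roi_name)
  partition <- detect_communities(graph, n_restarts = config$n_community_restarts,
                                  seed = child_seed(seed, 2))
  list(roi_series = roi_ts, subject_r = subject_r, mean_r = mean_r,
       perm = perm, graph = graph, partition = partition)
}

#' Simulate and map a full study one subject at a time
#'
#' Memory-lean variant of [simulate_study()] + [run_overlap_analysis()]:
#' each subject's BOLD series is generated, fit under both analysis
#' strategies (combined GLM on original regressors; per-feature GLMs on
#' orthogonalized regressors), and discarded, keeping only the beta maps.
#' Subject data are identical to a [simulate_study()] run with the same
#' seed.
#'
#' @inheritParams simulate_study
#' @param social Social features counted in the overlap maps.
#' @return List: `overlap_original`, `overlap_orthogonalized`, `group_original`,
#'   `group_orthogonalized`, `truth`, `subject_betas`, `design`, `design_orth`,
#'   `rating_set`, `rho` (per-subject estimates), `config`.
#' @export
simulate_and_map <- function(config = run_config(), n_subjects = 19,
                             n_volumes_total = 770, n_discard = 2,
                             shape = c(24, 24, 24), voxel_mm = 4,
                             amplitude = 1, noise_sd = 2, ar1_rho = 0.4,
                             subject_sd = 0.25, n_clips = 137, seed = NULL,
                             social = social_features()) {
  nt <- n_volumes_total - n_discard
  rs <- generate_ratings(n_clips = n_clips, rate_hz = config$rating_rate_hz,
                         seed = child_seed(seed, 1))
  regressors <- ratings_to_regressors(rs, tr_s = config$tr_s, n_volumes = nt)
  design <- build_design_matrix(regressors, tr_s = config$tr_s,
                                highpass_cutoff_s = config$highpass_cutoff_s,
                                hrf_mode = config$hrf_mode)
  design_orth <- build_design_matrix(regressors, tr_s = config$tr_s,
                                     highpass_cutoff_s = config$highpass_cutoff_s,
                                     hrf_mode = config$hrf_mode,
                                     orthogonalize = TRUE,
                                     ortho_stage = config$ortho_stage)
  truth <- ground_truth_regions(shape = shape, voxel_mm = voxel_mm,
                                amplitude = amplitude)
  fits_orig <- vector("list", n_subjects)
  fits_orth <- vector("list", n_subjects)
  betas <- vector("list", n_subjects)
  rho <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    bold <- generate_bold(design, truth, n_subjects = n_subjects,
                          noise_sd = noise_sd, ar1_rho = ar1_rho,
                          subject_sd = subject_sd, tr_s = config$tr_s,
                          n_discarded = n_discard,
                          seed = child_seed(seed, 2), subjects = s)
    truth <- bold$truth
    dual <- fit_subject_dual(bold$series[[1]], design, design_orth)
    fits_orig[[s]] <- dual$original
    fits_orth[[s]] <- dual$orthogonalized
    betas[[s]] <- bold$subject_betas
    rho[s] <- dual$original$rho
    rm(bold, dual)
  }
  names(fits_orig) <- names(fits_orth) <- sprintf("sub_%02d", seq_len(n_subjects))
  grp_orig <- group_feature_maps(fits_orig, q = config$fdr_q, features = social)
  grp_orth <- group_feature_maps(fits_orth, q = config$fdr_q, features = social)
  list(
    overlap_original = overlap_map(lapply(grp_orig, `[[`, "significance")),
    overlap_orthogonalized = overlap_map(lapply(grp_orth, `[[`, "significance")),
    group_original = grp_orig,
    group_orthogonalized = grp_orth,
    fits_original = fits_orig,
    fits_orthogonalized = fits_orth,
    truth = truth,
    subject_betas = dplyr::bind_rows(betas),
    design = design,
    design_orth = design_orth,
    rating_set = rs,
    rho = rho,
    config = config
  )
}

# Shared-workspace subject fit for the two overlap strategies: the data are
# loaded and AR(1)-whitened once (rho from the combined-model OLS residuals)
# and both beta sets are computed on the shared whitened data.
fit_subject_dual <- function(series, design, design_orth, ar1_max_voxels = 2000) {
  d <- dim(series$data)
  nt <- d[4]
  mask_idx <- which(series$mask)
  yv <- matrix(series$data, prod(d[1:3]), nt)[mask_idx, , drop = FALSE]
  x_full <- design_full_matrix(design)
  qx0 <- qr(x_full)
  if (qx0$rank < ncol(x_full)) stop_socmap("design matrix is rank deficient", "collinearity")
  sub <- unique(round(seq(1, length(mask_idx),
                          length.out = min(ar1_max_voxels, length(mask_idx)))))
  ar1 <- refine_ar1(cbind(design$features, `(intercept)` = 1),
                    t(yv[sub, , drop = FALSE]))
  rho <- ar1$rho
  # whiten along time (columns of the voxel x time matrix)
  yw <- cbind(sqrt(1 - rho^2) * yv[, 1], yv[, -1] - rho * yv[, -nt, drop = FALSE])
  # combined GLM on the original regressors: beta' = Y W X (X'X)^-1
  xw <- ar1_whiten(x_full, rho)
  beta_comb <- t(yw %*% xw %*% chol2inv(chol(crossprod(xw))))
  rownames(beta_comb) <- colnames(x_full)
  fit_orig <- build_first_level_fit(
    list(beta = beta_comb, se = NULL, df = nrow(xw) - ncol(xw)),
    design, series, rho, kappa(xw[, feature_names(design), drop = FALSE], exact = FALSE)
  )
  # per-feature GLMs on the orthogonalized regressors (Frisch-Waugh)
  xo <- ar1_whiten(design_orth$features, rho)
  nw <- ar1_whiten(cbind(design_orth$drift, `(intercept)` = 1), rho)
  qn <- qr(nw)
  qmat <- qr.Q(qn)
  yr <- yw - (yw %*% qmat) %*% t(qmat)
  xr <- xo - qmat %*% crossprod(qmat, xo)
  sxx <- colSums(xr^2)
  beta_orth <- t(yr %*% xr) / sxx
  rownames(beta_orth) <- colnames(xo)
  fit_orth <- build_first_level_fit(
    list(beta = beta_orth, se = NULL, df = nrow(xo) - qn$rank - 1L),
    design_orth, series, rho, kappa(xo, exact = FALSE)
  )
  list(original = fit_orig, orthogonalized = fit_orth)
}

#' Value of a map at the voxel nearest a world coordinate
#'
#' @param map A [stat_map()].
#' @param center_mm World (mm) coordinate.
#' @return The voxel value.
#' @export
map_value_at <- function(map, center_mm) {
  idx <- world_to_index(map$affine, center_mm)
  map$values[idx[1], idx[2], idx[3]]
}

#' Region-wise summary of an overlap map
#'
#' Maximum (and center) overlap count within each planted region of a
#' ground truth — the quantity used to check hub recovery.
#'
#' @param overlap An overlap [stat_map()].
#' @param truth A [ground_truth_regions()] object on the same grid.
#' @return Tibble (`region`, `type`, `center_overlap`, `max_overlap`).
#' @export
overlap_by_region <- function(overlap, truth) {
  purrr::map_dfr(seq_len(nrow(truth$regions)), function(i) {
    idx <- which(truth$region_labels == i)
    tibble::tibble(
      region = truth$regions$region[i],
      type = truth$regions$type[i],
      center_overlap = map_value_at(
        overlap,
        c(truth$regions$x[i], truth$regions$y[i], truth$regions$z[i])
      ),
      max_overlap = max(overlap$values[idx])
    )
  })
}
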