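#' Planted ground-truth effect geometry
#'
#' Builds the default desk-scale ground truth: a 24 x 24 x 24 grid at 4 mm
#' with spherical planted regions — one "hub" responding to all eight social
#' features and to none of the non-social ones, four specialized regions
#' responding to subsets of social features (mirroring partially segregated
#' networks for faces/interaction/speech, bodies/motion/action/pain,
#' emotion/pain, and interaction/speech), two non-social regions, and null
#' background.
#'
#' @param shape Spatial grid dimensions (default `c(24, 24, 24)`).
#' @param voxel_mm Isotropic voxel size in mm (default 4).
#' @param features Feature tibble ([default_features()]).
#' @param amplitude Planted effect size (beta units, default 1).
#' @param region_radius_mm Radius of each planted sphere (default 8 mm).
#' @return A `ground_truth`: `beta_true` (x,y,z,feature array),
#'   `region_labels` (integer array), `regions` (tibble), `affine`, plus the
#'   noise parameters filled in by [generate_bold()].
#' @export
ground_truth_regions <- function(shape = c(24, 24, 24), voxel_mm = 4,
                                 features = default_features(),
                                 amplitude = 1, region_radius_mm = 8) {
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -voxel_mm * (shape - 1) / 2
  fn <- features$feature
  regions <- tibble::tibble(
    region = c("hub", "face_voice_net", "body_action_net", "pain_emotion_net",
               "interaction_net", "scene_region", "object_motion_region"),
    type = c("hub", "specialized", "specialized", "specialized", "specialized",
             "nonsocial", "nonsocial"),
    x = c(0, -26, 26, -24, 24, 0, 0),
    y = c(-30, 20, 20, -24, -24, 26, -30),
    z = c(14, 12, -16, -12, 16, -18, -22),
    radius_mm = region_radius_mm,
    features = list(
      fn[features$social],
      c("faces", "social_interaction", "speech"),
      c("bodies", "biological_motion", "goal_oriented_action", "pain"),
      c("emotion", "pain"),
      c("social_interaction", "speech", "emotion"),
      c("places", "objects"),
      c("rigid_motion", "non_goal_action")
    )
  )
  # brain mask: sphere covering the grid faces; all regions lie inside
  brain_mask <- sphere_mask(c(0, 0, 0), voxel_mm * min(shape) / 2, affine, shape)
  beta_true <- array(0, dim = c(shape, length(fn)),
                     dimnames = list(NULL, NULL, NULL, fn))
  labels <- array(0L, dim = shape)
  for (i in seq_len(nrow(regions))) {
    ball <- sphere_mask(c(regions$x[i], regions$y[i], regions$z[i]),
                        regions$radius_mm[i], affine, shape) & brain_mask
    labels[ball] <- i
    for (f in regions$features[[i]]) {
      slab <- beta_true[, , , f]
      slab[ball] <- amplitude
      beta_true[, , , f] <- slab
    }
  }
  structure(
    list(
      beta_true = beta_true, region_labels = labels, regions = regions,
      affine = affine, shape = shape, features = features,
      brain_mask = brain_mask,
      amplitude = amplitude,
      ar1_rho_true = NA_real_, noise_sd = NA_real_, subject_sd = NA_real_
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %s grid, %d planted regions (amplitude %g), rho = %s\n",
    paste(x$shape, collapse = "x"), nrow(x$regions), x$amplitude,
    format(x$ar1_rho_true)
  ))
  invisible(x)
}

#' Generate synthetic BOLD series with planted effects
#'
#' Each voxel's time series is the design-weighted sum of its planted betas
#' plus stationary AR(1) Gaussian noise; per-subject betas are jittered
#' around `beta_true` (multiplicatively on active voxels) to create a
#' random-effects structure. Optional isotropic Gaussian smoothing can be
#' applied to the result.
#'
#' @param design A [build_design_matrix()] result; its feature columns drive
#'   the signal.
#' @param truth A [ground_truth_regions()] object.
#' @param n_subjects Number of subjects.
#' @param noise_sd SD of the AR(1) innovation-driven noise (marginal SD).
#' @param ar1_rho AR(1) coefficient of the noise, |rho| < 1.
#' @param subject_sd SD of the per-subject beta jitter (additive, applied to
#'   planted non-zero betas).
#' @param smooth_fwhm_mm Isotropic Gaussian smoothing FWHM (0 = none).
#' @param tr_s Repetition time recorded in the output series.
#' @param n_discarded Discard count recorded in the output series.
#' @param seed Base seed; subject i uses [child_seed()] stream i.
#' @param subjects Subject indices to generate (default all); subject i is
#'   identical whether generated alone or with the rest, so large studies
#'   can be streamed one subject at a time.
#' @return List: `series` (list of [volume_series()]), `subject_betas`
#'   (tibble: subject, region, feature, beta), `truth` (with noise fields
#'   filled in).
#' @export
generate_bold <- function(design, truth, n_subjects = 19, noise_sd = 2,
                          ar1_rho = 0.4, subject_sd = 0.25,
                          smooth_fwhm_mm = 0, tr_s = design$tr_s,
                          n_discarded = 2L, seed = NULL,
                          subjects = seq_len(n_subjects)) {
  if (abs(ar1_rho) >= 1) stop_socmap("|ar1_rho| must be < 1", "stability")
  x <- design$features
  nt <- nrow(x)
  shape <- truth$shape
  nvox <- prod(shape)
  fn <- colnames(x)
  if (!identical(sort(fn), sort(dimnames(truth$beta_true)[[4]]))) {
    stop_socmap("design features do not match ground-truth features", "validation")
  }
  brain <- truth$brain_mask %||% array(TRUE, dim = shape)
  brain_idx <- which(brain)
  active <- truth$region_labels > 0
  active_idx <- which(active)
  beta_flat <- matrix(truth$beta_true, nrow = nvox)[active_idx, , drop = FALSE]
  colnames(beta_flat) <- dimnames(truth$beta_true)[[4]]
  beta_flat <- beta_flat[, fn, drop = FALSE]
  region_of <- truth$region_labels[active_idx]
  innov_scale <- noise_sd * sqrt(1 - ar1_rho^2)
  series <- vector("list", length(subjects))
  subject_betas <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    series_s <- with_seed(child_seed(seed, s), {
      jit <- matrix(rnorm(nrow(truth$regions) * length(fn), 0, subject_sd),
                    nrow(truth$regions), length(fn), dimnames = list(NULL, fn))
      beta_s <- beta_flat + jit[region_of, , drop = FALSE] * (beta_flat != 0)
      nb <- length(brain_idx)
      # stationary AR(1) over time, voxels only inside the brain mask
      m <- matrix(rnorm(nb * nt, 0, innov_scale), nb, nt)
      state <- rnorm(nb, 0, noise_sd)
      for (t in seq_len(nt)) {
        state <- ar1_rho * state + m[, t]
        m[, t] <- state
      }
      sig_rows <- match(active_idx, brain_idx)
      m[sig_rows, ] <- m[sig_rows, , drop = FALSE] + tcrossprod(beta_s, x)
      arr <- matrix(0, nvox, nt)
      arr[brain_idx, ] <- m
      dim(arr) <- c(shape, nt)
      if (smooth_fwhm_mm > 0) {
        arr <- smooth_gaussian_4d(arr, smooth_fwhm_mm, abs(truth$affine[1, 1]))
      }
      list(arr = arr, beta_s = beta_s)
    })
    series[[si]] <- volume_series(
      data = series_s$arr, affine = truth$affine, tr_s = tr_s,
      mask = brain,
      subject_id = sprintf("sub_%02d", s), n_discarded = n_discarded
    )
    bt <- region_beta_table(series_s$beta_s, region_of, nrow(truth$regions), fn)
    subject_betas[[si]] <- tibble::tibble(
      subject = sprintf("sub_%02d", s),
      region = rep(truth$regions$region, each = length(fn)),
      feature = rep(fn, times = nrow(truth$regions)),
      beta = as.vector(t(bt))
    )
  }
  truth$ar1_rho_true <- ar1_rho
  truth$noise_sd <- noise_sd
  truth$subject_sd <- subject_sd
  list(
    series = series,
    subject_betas = dplyr::bind_rows(subject_betas),
    truth = truth
  )
}

# Region x feature matrix of the (constant within region) subject betas.
region_beta_table <- function(beta_s, region_of, n_regions, fn) {
  out <- matrix(0, n_regions, length(fn), dimnames = list(NULL, fn))
  for (r in seq_len(n_regions)) {
    rows <- which(region_of == r)
    if (length(rows) > 0) out[r, ] <- beta_s[rows[1], ]
  }
  out
}

# Separable isotropic Gaussian smoothing of a 4D array (per volume).
smooth_gaussian_4d <- function(arr, fwhm_mm, voxel_mm) {
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(3 * sigma_vox))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  kern <- kern / sum(kern)
  d <- dim(arr)
  sm1 <- function(m) {
    # smooth along rows of a (dim_along x rest) matrix with reflection padding
    padded <- rbind(m[rev(seq_len(half)), , drop = FALSE], m,
                    m[nrow(m) - seq_len(half) + 1L, , drop = FALSE])
    out <- stats::filter(padded, kern, method = "convolution", sides = 2)
    out[(half + 1):(half + nrow(m)), , drop = FALSE]
  }
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:4, axis))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- matrix(a, nrow = da[1])
    a <- sm1(a)
    a <- array(a, dim = da)
    arr <- aperm(a, order(perm))
  }
  arr
}
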