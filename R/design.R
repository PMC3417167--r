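#' Canonical double-gamma hemodynamic response
#'
#' The canonical HRF as a difference of two gamma densities (response peak
#' near 5 s, undershoot near 15 s, undershoot ratio 1/6), normalized to unit
#' peak.
#'
#' @param t_s Time points in seconds (>= 0).
#' @param peak_delay Shape of the response gamma (default 6).
#' @param undershoot_delay Shape of the undershoot gamma (default 16).
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @return HRF values at `t_s`.
#' @export
hrf_canonical <- function(t_s, peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 1 / 6) {
  h <- function(t) {
    stats::dgamma(t, shape = peak_delay, rate = 1) -
      undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  }
  fine <- seq(0, 40, by = 0.01)
  h(t_s) / max(h(fine))
}

#' Convolve a feature time course with the canonical HRF
#'
#' Causal convolution with the double-gamma response sampled on the
#' acquisition grid, truncated to the original length. `mode = "none"` is the
#' identity (the regressors enter the model as raw ratings).
#'
#' @param timecourses Tibble (`feature`, `volume_index`, `value`) or a
#'   time x feature matrix.
#' @param tr_s Repetition time in seconds.
#' @param mode `"canonical"` or `"none"`.
#' @return Object of the same shape as the input (provenance `"convolved"`).
#' @export
hrf_convolve <- function(timecourses, tr_s, mode = c("canonical", "none")) {
  mode <- match.arg(mode)
  m <- timecourse_matrix(timecourses)
  if (mode == "canonical") {
    kern <- hrf_canonical(seq(0, 32, by = tr_s))
    m <- apply(m, 2, convolve_causal, kernel = kern)
  }
  if (is.matrix(timecourses)) {
    colnames(m) <- colnames(timecourses)
    return(m)
  }
  out <- timecourse_tibble(m)
  attr(out, "tr_s") <- tr_s
  attr(out, "provenance") <- if (mode == "none") attr(timecourses, "provenance") else "convolved"
  out
}

convolve_causal <- function(x, kernel) {
  n <- length(x)
  k <- length(kernel)
  padded <- c(rep(0, k - 1), x)
  as.numeric(stats::filter(padded, kernel, method = "convolution", sides = 1))[k:(k + n - 1)]
}

#' Discrete-cosine high-pass drift basis
#'
#' Orthonormal DCT-II columns whose periods exceed the cutoff; the number of
#' columns is `K = floor(2 * n * tr_s / cutoff_s)`. With `cutoff_s >= 2 * n *
#' tr_s` the basis is empty (intercept only).
#'
#' @param n_volumes Number of time points.
#' @param tr_s Repetition time in seconds.
#' @param cutoff_s High-pass cutoff period in seconds.
#' @return An `n_volumes` x K matrix (possibly K = 0) with orthonormal columns.
#' @export
dct_highpass_basis <- function(n_volumes, tr_s, cutoff_s) {
  if (n_volumes < 2) stop_socmap("need at least 2 volumes for a drift basis", "validation")
  if (cutoff_s <= 2 * tr_s) {
    stop_socmap("cutoff_s must exceed 2 * tr_s", "validation")
  }
  k_max <- floor(2 * n_volumes * tr_s / cutoff_s)
  t0 <- seq_len(n_volumes) - 1
  cols <- vapply(
    seq_len(k_max),
    function(k) sqrt(2 / n_volumes) * cos(pi * (2 * t0 + 1) * k / (2 * n_volumes)),
    numeric(n_volumes)
  )
  m <- matrix(cols, nrow = n_volumes, ncol = k_max)
  if (k_max > 0) colnames(m) <- paste0("dct_", seq_len(k_max))
  m
}

#' Orthogonalize one feature against the other original regressors
#'
#' Least-squares fit of feature `f` on the remaining original feature
#' columns (plus an intercept); the residual is the orthogonalized
#' regressor. Positive (negative) weights mark features that were subtracted
#' from (added to) the original time course. The drift basis is excluded
#' from the fit.
#'
#' @param feature Feature name (a column of `x`).
#' @param x Time x feature matrix of the original regressors.
#' @return List with `residual`, `weights` (named, over the other features),
#'   `intercept`, and `r_squared` of the fit.
#' @export
orthogonalize_feature <- function(feature, x) {
  if (!feature %in% colnames(x)) {
    stop_socmap(sprintf("feature '%s' is not a column of x", feature), "validation")
  }
  others <- setdiff(colnames(x), feature)
  xo <- cbind(`(intercept)` = 1, x[, others, drop = FALSE])
  qx <- qr(xo)
  if (qx$rank < ncol(xo)) {
    dep <- colnames(xo)[qx$pivot[seq_len(ncol(xo)) > qx$rank]]
    stop_socmap(
      paste0("other regressors are rank deficient; dependent set: ",
             paste(dep, collapse = ", ")),
      "collinearity"
    )
  }
  y <- x[, feature]
  coefs <- qr.coef(qx, y)
  fit <- drop(xo %*% coefs)
  res <- y - fit
  ssy <- sum((y - mean(y))^2)
  r2 <- if (ssy > 0) 1 - sum(res^2) / ssy else NA_real_
  list(
    residual = res,
    weights = coefs[others],
    intercept = coefs[["(intercept)"]],
    r_squared = r2
  )
}

#' Mutually orthogonalize all feature regressors
#'
#' Each feature is residualized against all the other *original* regressors
#' simultaneously (not sequentially), so the result does not depend on
#' feature order. The ledger records, per feature, the fitting weights on
#' every other feature and the R^2 of the fit.
#'
#' @param x Time x feature matrix of original regressors.
#' @return List with `residuals` (same shape as `x`) and `ledger` (tibble:
#'   `feature`, `other`, `weight`, `intercept`, `r_squared`).
#' @export
orthogonalize_features <- function(x) {
  feats <- colnames(x)
  fits <- lapply(feats, orthogonalize_feature, x = x)
  residuals <- vapply(fits, `[[`, numeric(nrow(x)), "residual")
  colnames(residuals) <- feats
  ledger <- purrr::map2_dfr(feats, fits, function(f, fit) {
    tibble::tibble(
      feature = f,
      other = names(fit$weights),
      weight = unname(fit$weights),
      intercept = fit$intercept,
      r_squared = fit$r_squared
    )
  })
  list(residuals = residuals, ledger = ledger)
}

#' Build a first-level design matrix
#'
#' Assembles feature regressors (optionally HRF-convolved and/or mutually
#' orthogonalized), the discrete-cosine drift basis, and an intercept.
#' Orthogonalization is applied to the rating time courses before HRF
#' convolution by default (`ortho_stage = "pre_hrf"`); `"post_hrf"`
#' residualizes the convolved regressors instead, which keeps the residuals
#' exactly orthogonal in the fitted space.
#'
#' @param timecourses Tibble (`feature`, `volume_index`, `value`) on the
#'   acquisition grid, or a time x feature matrix.
#' @param tr_s Repetition time (seconds).
#' @param highpass_cutoff_s Drift cutoff (seconds).
#' @param hrf_mode `"canonical"` or `"none"`.
#' @param orthogonalize Mutually orthogonalize the feature regressors?
#' @param ortho_stage `"pre_hrf"` or `"post_hrf"`.
#' @return A `design_matrix` object: feature columns, drift columns,
#'   intercept, and the orthogonalization ledger (if any).
#' @export
build_design_matrix <- function(timecourses, tr_s, highpass_cutoff_s = 128,
                                hrf_mode = c("canonical", "none"),
                                orthogonalize = FALSE,
                                ortho_stage = c("pre_hrf", "post_hrf")) {
  hrf_mode <- match.arg(hrf_mode)
  ortho_stage <- match.arg(ortho_stage)
  x <- timecourse_matrix(timecourses)
  ledger <- NULL
  if (orthogonalize && ortho_stage == "pre_hrf") {
    o <- orthogonalize_features(x)
    x <- o$residuals
    ledger <- o$ledger
  }
  x <- hrf_convolve(x, tr_s = tr_s, mode = hrf_mode)
  if (orthogonalize && ortho_stage == "post_hrf") {
    o <- orthogonalize_features(x)
    x <- o$residuals
    ledger <- o$ledger
  }
  drift <- dct_highpass_basis(nrow(x), tr_s, highpass_cutoff_s)
  structure(
    list(
      features = x,
      drift = drift,
      tr_s = tr_s,
      hrf_mode = hrf_mode,
      orthogonalized = isTRUE(orthogonalize),
      ortho_stage = if (orthogonalize) ortho_stage else NA_character_,
      ortho_ledger = ledger
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "<design_matrix> %d volumes, %d features (%s%s), %d drift columns + intercept\n",
    nrow(x$features), ncol(x$features),
    x$hrf_mode,
    if (x$orthogonalized) sprintf(", orthogonalized %s", x$ortho_stage) else "",
    ncol(x$drift)
  ))
  invisible(x)
}

design_full_matrix <- function(design) {
  cbind(design$features, design$drift, `(intercept)` = 1)
}

feature_names <- function(design) colnames(design$features)

#' Compare original and orthogonalized analyses
#'
#' Per feature: the spatial Pearson correlation between the t-maps of the
#' original and orthogonalized GLMs (over in-mask voxels) and the temporal
#' correlation between the original and orthogonalized regressors.
#'
#' @param tmaps_orig,tmaps_orth Named lists of t [stat_map()]s (same grid).
#' @param x,x_orth Time x feature matrices of original and orthogonalized
#'   regressors.
#' @return Tibble (`feature`, `spatial_r`, `temporal_r`).
#' @export
compare_orthogonalization <- function(tmaps_orig, tmaps_orth, x, x_orth) {
  feats <- intersect(names(tmaps_orig), names(tmaps_orth))
  purrr::map_dfr(feats, function(f) {
    a <- tmaps_orig[[f]]
    b <- tmaps_orth[[f]]
    check_same_geometry(a$affine, b$affine, dim(a$values), dim(b$values), "t-maps")
    va <- in_mask_values(a)
    vb <- in_mask_values(b)
    keep <- is.finite(va) & is.finite(vb)
    if (sd(va[keep]) == 0 || sd(vb[keep]) == 0) {
      stop_socmap("zero-variance t-map: spatial correlation undefined",
                  "undefined_correlation")
    }
    tibble::tibble(
      feature = f,
      spatial_r = cor(va[keep], vb[keep]),
      temporal_r = cor(x[, f], x_orth[, f])
    )
  })
}
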