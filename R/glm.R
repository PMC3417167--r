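#' Pooled AR(1) noise model
#'
#' Pooled lag-1 autocorrelation of residuals across in-mask voxels: one
#' global rho per subject, estimated from OLS residuals, used to prewhiten
#' data and design before the final least-squares pass.
#'
#' @param residuals Time x voxel matrix of residuals (>= 3 time points).
#' @return An `ar1_model` list with `rho`, `n_time`, `n_voxels`.
#' @export
estimate_ar1 <- function(residuals) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 3) {
    stop_socmap("AR(1) estimation needs at least 3 time points", "validation")
  }
  mu <- colMeans(residuals)
  v <- colSums(residuals^2) / nrow(residuals) - mu^2
  keep <- which(v > 1e-300)
  if (length(keep) == 0) {
    stop_socmap("all residual series have zero variance", "degenerate")
  }
  r <- residuals[, keep, drop = FALSE]
  r <- sweep(r, 2, colMeans(r))
  num <- sum(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE])
  den <- sum(r^2)
  structure(
    list(rho = num / den, n_time = nrow(r), n_voxels = length(keep)),
    class = "ar1_model"
  )
}

#' @rdname estimate_ar1
#' @param rho Known AR(1) coefficient (|rho| < 1), e.g. 0 for plain OLS.
#' @export
ar1_model <- function(rho) {
  if (abs(rho) >= 1) stop_socmap("|rho| must be < 1", "stability")
  structure(list(rho = rho, n_time = NA_integer_, n_voxels = NA_integer_),
            class = "ar1_model")
}

#' @export
print.ar1_model <- function(x, ...) {
  cat(sprintf("<ar1_model> rho = %.4f (pooled over %d voxels, T = %d)\n",
              x$rho, x$n_voxels, x$n_time))
  invisible(x)
}

# Iteratively refined AR(1) coefficient for prewhitening: re-estimates the
# pooled lag-1 autocorrelation of the whitened-model OLS residuals and steps
# rho until it vanishes. The estimation model should exclude the drift
# basis, which otherwise absorbs the low-frequency AR(1) power and biases
# rho downward (the fit itself still includes the drift columns).
refine_ar1 <- function(x, y_sub, n_iter = 3) {
  a <- 0
  model <- NULL
  for (i in seq_len(n_iter)) {
    xw <- if (a != 0) ar1_whiten(x, a) else x
    yw <- if (a != 0) ar1_whiten(y_sub, a) else y_sub
    model <- estimate_ar1(qr.resid(qr(xw), yw))
    a <- max(min(a + model$rho * (1 - abs(a)), 0.99), -0.99)
  }
  structure(list(rho = a, n_time = model$n_time, n_voxels = model$n_voxels),
            class = "ar1_model")
}

#' Exact AR(1) prewhitening filter
#'
#' Applies the exact whitening transform for stationary AR(1) noise with
#' coefficient `rho`: the first sample is scaled by `sqrt(1 - rho^2)` and
#' every later sample becomes `x_t - rho * x_(t-1)`. With `rho = 0` this is
#' the identity.
#'
#' @param x Numeric vector or time x voxel matrix.
#' @param rho AR(1) coefficient, |rho| < 1.
#' @return Whitened object of the same shape.
#' @export
ar1_whiten <- function(x, rho) {
  if (abs(rho) >= 1) stop_socmap("|rho| must be < 1", "stability")
  vec <- is.null(dim(x))
  m <- as.matrix(x)
  out <- rbind(
    sqrt(1 - rho^2) * m[1, , drop = FALSE],
    m[-1, , drop = FALSE] - rho * m[-nrow(m), , drop = FALSE]
  )
  if (vec) drop(out) else out
}

#' First-level mass-univariate GLM with AR(1) prewhitening
#'
#' Fits every in-mask voxel's time series on the design (features + drift +
#' intercept). Both data and design are prewhitened by the pooled AR(1)
#' filter, then solved by voxelwise ordinary least squares;
#' `t = beta / se` with `df = T - rank(X)` and two-sided p values. When
#' `ar1` is `NULL`, rho is first estimated from OLS residuals on a
#' deterministic subset of in-mask voxels.
#'
#' @param series A [volume_series()].
#' @param design A [build_design_matrix()] result (row count must match).
#' @param ar1 An [estimate_ar1()] model, or `NULL` to estimate internally.
#' @param ar1_max_voxels Voxel budget for internal rho estimation.
#' @param statistics `"full"` (beta, t, p) or `"beta_only"` (skip standard
#'   errors, e.g. when only subject betas feed a second-level test).
#' @return A `first_level_fit`: per-feature `beta`, `t`, `p` [stat_map()]s,
#'   plus `rho`, `df`, and the design condition number.
#' @export
fit_glm <- function(series, design, ar1 = NULL, ar1_max_voxels = 2000,
                    statistics = c("full", "beta_only")) {
  statistics <- match.arg(statistics)
  x <- design_full_matrix(design)
  if (nrow(x) != n_volumes(series)) {
    stop_socmap("design rows do not match the number of volumes", "alignment")
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop_socmap("design matrix is rank deficient", "collinearity")
  }
  y <- series_matrix(series)
  mask_idx <- which(series$mask)
  ym <- y[, mask_idx, drop = FALSE]
  if (is.null(ar1)) {
    sub <- mask_idx[unique(round(seq(1, length(mask_idx),
                                     length.out = min(ar1_max_voxels, length(mask_idx)))))]
    ar1 <- refine_ar1(cbind(design$features, `(intercept)` = 1),
                      y[, sub, drop = FALSE])
  }
  rho <- ar1$rho
  xw <- ar1_whiten(x, rho)
  yw <- ar1_whiten(ym, rho)
  fit <- solve_ols(xw, yw, se = statistics == "full")
  build_first_level_fit(fit, design, series, rho,
                        kappa(xw[, seq_len(ncol(design$features)), drop = FALSE],
                              exact = FALSE))
}

# Dense OLS for a multi-voxel response matrix; returns beta, se, t, df.
# The residual sum of squares comes from the QR effects (no residual GEMM).
solve_ols <- function(x, y, se = TRUE) {
  qx <- qr(x)
  beta <- qr.coef(qx, y)
  df <- nrow(x) - qx$rank
  if (!se) return(list(beta = beta, se = NULL, df = df))
  qty <- qr.qty(qx, y)
  rss <- colSums(y^2) - colSums(qty[seq_len(qx$rank), , drop = FALSE]^2)
  rss <- pmax(rss, 0)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se_m <- sqrt(outer(diag(xtx_inv), rss / df))
  rownames(se_m) <- colnames(x)
  list(beta = beta, se = se_m, df = df)
}

build_first_level_fit <- function(fit, design, series, rho, cond) {
  feats <- feature_names(design)
  sp <- dim(series$data)[1:3]
  mask_idx <- which(series$mask)
  make_map <- function(vals, kind, f, df = NA_real_) {
    arr <- array(NaN, dim = sp)
    arr[mask_idx] <- vals
    stat_map(arr, kind, series$affine, mask = series$mask, feature = f,
             level = "first", df = df)
  }
  maps <- lapply(feats, function(f) {
    b <- fit$beta[f, ]
    if (is.null(fit$se)) {
      return(list(beta = make_map(b, "beta", f), t = NULL, p = NULL, se = NULL))
    }
    se <- fit$se[f, ]
    tval <- ifelse(se > 0, b / se, 0)
    pval <- 2 * pt(-abs(tval), df = fit$df)
    list(
      beta = make_map(b, "beta", f),
      t = make_map(tval, "t", f, fit$df),
      p = make_map(pval, "p", f, fit$df),
      se = se
    )
  })
  names(maps) <- feats
  structure(
    list(
      beta = lapply(maps, `[[`, "beta"),
      t = lapply(maps, `[[`, "t"),
      p = lapply(maps, `[[`, "p"),
      rho = rho,
      df = fit$df,
      condition_number = cond,
      subject_id = series$subject_id,
      features = feats
    ),
    class = "first_level_fit"
  )
}

#' @export
print.first_level_fit <- function(x, ...) {
  cat(sprintf(
    "<first_level_fit '%s'> %d features, df = %d, rho = %.3f, kappa = %.2f\n",
    x$subject_id, length(x$features), x$df, x$rho, x$condition_number
  ))
  invisible(x)
}

#' First-level fit in per-feature or combined mode
#'
#' `"combined"` fits all features in one GLM (every other feature is a
#' covariate). `"per_feature"` fits each feature in its own GLM with only the
#' drift basis and intercept as covariates, mirroring analyses in which each
#' feature is analyzed separately; it is computed through the
#' Frisch-Waugh projection against the shared nuisance block, which is
#' algebraically identical to fitting the separate GLMs.
#'
#' @inheritParams fit_glm
#' @param mode `"combined"` or `"per_feature"`.
#' @return A `first_level_fit`.
#' @export
fit_first_level <- function(series, design, mode = c("combined", "per_feature"),
                            ar1 = NULL, ar1_max_voxels = 2000,
                            statistics = c("full", "beta_only")) {
  mode <- match.arg(mode)
  statistics <- match.arg(statistics)
  if (mode == "combined") {
    return(fit_glm(series, design, ar1, ar1_max_voxels, statistics))
  }
  xf <- design$features
  nuis <- cbind(design$drift, `(intercept)` = 1)
  if (nrow(xf) != n_volumes(series)) {
    stop_socmap("design rows do not match the number of volumes", "alignment")
  }
  y <- series_matrix(series)
  mask_idx <- which(series$mask)
  ym <- y[, mask_idx, drop = FALSE]
  if (is.null(ar1)) {
    sub <- mask_idx[unique(round(seq(1, length(mask_idx),
                                     length.out = min(ar1_max_voxels, length(mask_idx)))))]
    ar1 <- refine_ar1(cbind(xf, `(intercept)` = 1), y[, sub, drop = FALSE])
  }
  rho <- ar1$rho
  xw <- ar1_whiten(xf, rho)
  nw <- ar1_whiten(nuis, rho)
  yw <- ar1_whiten(ym, rho)
  qn <- qr(nw)
  rank_n <- qn$rank
  yr <- qr.resid(qn, yw)
  xr <- qr.resid(qn, xw)
  df <- nrow(xw) - rank_n - 1L
  want_se <- statistics == "full"
  ssy <- if (want_se) colSums(yr^2)
  feats <- colnames(xf)
  beta <- matrix(NA_real_, length(feats), ncol(yr), dimnames = list(feats, NULL))
  se <- if (want_se) beta
  for (f in feats) {
    xc <- xr[, f]
    sxx <- sum(xc^2)
    if (sxx <= 0) stop_socmap(sprintf("regressor '%s' lies in the nuisance span", f),
                              "collinearity")
    b <- drop(crossprod(xc, yr)) / sxx
    beta[f, ] <- b
    if (want_se) {
      rss <- pmax(ssy - b^2 * sxx, 0)
      se[f, ] <- sqrt(rss / df / sxx)
    }
  }
  fit <- list(beta = beta, se = se, df = df)
  build_first_level_fit(fit, design, series, rho, kappa(xw, exact = FALSE))
}

#' Social versus non-social contrast
#'
#' Voxelwise `mean(social betas) - mean(non-social betas)` for one subject.
#'
#' @param beta_maps Named list of per-feature beta [stat_map()]s.
#' @param social,nonsocial Character vectors of feature names.
#' @return A contrast [stat_map()] (kind `"beta"`).
#' @export
social_vs_nonsocial_contrast <- function(beta_maps,
                                         social = social_features(),
                                         nonsocial = nonsocial_features()) {
  miss <- setdiff(c(social, nonsocial), names(beta_maps))
  if (length(miss) > 0) {
    stop_socmap(paste0("missing beta maps for: ", paste(miss, collapse = ", ")),
                "completeness")
  }
  ref <- beta_maps[[social[1]]]
  mean_arr <- function(set) {
    Reduce(`+`, lapply(beta_maps[set], `[[`, "values")) / length(set)
  }
  vals <- mean_arr(social) - mean_arr(nonsocial)
  stat_map(vals, "beta", ref$affine, mask = ref$mask,
           feature = "social_vs_nonsocial", level = "first")
}

#' @export
tidy.first_level_fit <- function(x, ...) {
  purrr::map_dfr(x$features, function(f) {
    tv <- in_mask_values(x$t[[f]])
    tibble::tibble(
      feature = f,
      max_abs_t = max(abs(tv)),
      n_voxels = length(tv),
      df = x$df
    )
  })
}

#' @export
glance.first_level_fit <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    n_features = length(x$features),
    rho = x$rho,
    df = x$df,
    condition_number = x$condition_number
  )
}
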