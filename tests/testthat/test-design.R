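test_that("HRF convolution is causal, linear, and peaks near 5 s", {
  tr <- 2.112
  n <- 40
  impulse <- matrix(c(1, rep(0, n - 1)), ncol = 1, dimnames = list(NULL, "f1"))
  out <- hrf_convolve(impulse, tr, "canonical")
  # closed-form double-gamma oracle, computed independently
  h <- function(t) dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6
  tg <- seq(0, 32, by = tr)
  oracle <- h(tg) / max(h(seq(0, 40, by = 0.01)))
  expect_equal(out[seq_along(tg), 1], oracle, tolerance = 1e-10)
  expect_equal(tg[which.max(out[, 1])], 4.224, tolerance = 1e-9)
  expect_lt(abs(5 - tg[which.max(out[, 1])]), tr) # peak within one TR of 5 s

  # mode "none" is the identity
  x <- make_regressors(nt = n, nf = 2)
  expect_equal(hrf_convolve(x, tr, "none"), x)

  # linearity
  a <- make_regressors(nt = n, nf = 1, seed = 21)
  b <- make_regressors(nt = n, nf = 1, seed = 22)
  expect_equal(
    hrf_convolve(a + b, tr, "canonical"),
    hrf_convolve(a, tr, "canonical") + hrf_convolve(b, tr, "canonical"),
    tolerance = 1e-12
  )
})

test_that("DCT drift basis has the stated column count and is orthonormal", {
  b <- dct_highpass_basis(768, 2.112, 128)
  expect_equal(ncol(b), 25) # floor(2 * 768 * 2.112 / 128)
  expect_equal(crossprod(b), diag(25), tolerance = 1e-10, ignore_attr = TRUE)
  # cutoff at/above twice the run length leaves intercept only
  expect_equal(ncol(dct_highpass_basis(100, 1, 2 * 100 * 1 + 1)), 0)
  expect_error(dct_highpass_basis(100, 2, 3), class = "socmap_error_validation")
  expect_error(dct_highpass_basis(1, 2, 128), class = "socmap_error_validation")
})

test_that("orthogonalization weights equal the normal-equation oracle", {
  x <- make_regressors(nt = 60, nf = 5, seed = 23)
  fit <- orthogonalize_feature("f2", x)
  others <- x[, c("f1", "f3", "f4", "f5")]
  xo <- cbind(1, others)
  oracle <- solve(crossprod(xo), crossprod(xo, x[, "f2"]))
  expect_equal(unname(fit$weights), unname(oracle[-1]), tolerance = 1e-10)
  expect_equal(fit$intercept, oracle[1], tolerance = 1e-10, ignore_attr = TRUE)
  # residual orthogonal to every other original column and the intercept
  expect_lt(max(abs(crossprod(fit$residual, others))),
            1e-8 * max(sqrt(colSums(others^2))))
  expect_lt(abs(sum(fit$residual)), 1e-8)
})

test_that("orthogonalization is a no-op for already-orthogonal features and
           detects perfect collinearity", {
  # mutually orthogonal, mean-zero columns (orthogonalized against intercept)
  x <- qr.Q(qr(cbind(1, make_regressors(nt = 50, nf = 3, seed = 24))))[, 2:4]
  colnames(x) <- paste0("f", 1:3)
  fit <- orthogonalize_feature("f1", x)
  expect_equal(max(abs(fit$weights)), 0, tolerance = 1e-8)
  expect_equal(fit$residual, x[, "f1"], tolerance = 1e-8, ignore_attr = TRUE)

  dup <- cbind(x, f4 = x[, "f1"])
  fit2 <- orthogonalize_feature("f1", dup)
  expect_lt(max(abs(fit2$residual)), 1e-10)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)
  # two identical *other* columns: rank-deficiency error names the set
  bad <- cbind(x, f4 = x[, "f2"])
  expect_error(orthogonalize_feature("f1", bad), class = "socmap_error_collinearity")
})

test_that("re-orthogonalizing a residual is the identity", {
  x <- make_regressors(nt = 80, nf = 4, seed = 25)
  fit <- orthogonalize_feature("f3", x)
  x2 <- x
  x2[, "f3"] <- fit$residual
  fit2 <- orthogonalize_feature("f3", x2)
  expect_equal(fit2$residual, fit$residual, tolerance = 1e-10)
  expect_lt(max(abs(fit2$weights)), 1e-10)
})

test_that("the ledger reconstructs every original regressor exactly", {
  x <- make_regressors(nt = 60, nf = 4, seed = 26)
  o <- orthogonalize_features(x)
  for (f in colnames(x)) {
    led <- dplyr::filter(o$ledger, .data$feature == f)
    rebuilt <- led$intercept[1] +
      drop(x[, led$other, drop = FALSE] %*% led$weight) +
      o$residuals[, f]
    expect_equal(rebuilt, unname(x[, f]), tolerance = 1e-10)
  }
})

test_that("drift columns leave feature betas unchanged on drift-free data", {
  nt <- 80
  x <- make_regressors(nt = nt, nf = 3, seed = 27)
  beta <- c(1.5, -0.7, 0.3)
  vs <- make_series(shape = c(3, 3, 3), nt = nt, seed = 28)
  sig <- drop(x %*% beta)
  vs$data <- array(rep(sig, each = 27), dim = c(3, 3, 3, nt))
  d_plain <- build_design_matrix(x, 2.112, highpass_cutoff_s = 1e6, hrf_mode = "none")
  d_drift <- build_design_matrix(x, 2.112, highpass_cutoff_s = 60, hrf_mode = "none")
  expect_gt(ncol(d_drift$drift), 0)
  f1 <- fit_glm(vs, d_plain, ar1 = ar1_model(0))
  f2 <- fit_glm(vs, d_drift, ar1 = ar1_model(0))
  for (i in 1:3) {
    expect_equal(in_mask_values(f2$beta[[i]]), in_mask_values(f1$beta[[i]]),
                 tolerance = 1e-8)
    expect_equal(in_mask_values(f1$beta[[i]]), rep(beta[i], 27), tolerance = 1e-8)
  }
})

test_that("orthogonalization comparison reports spatial and temporal r", {
  x <- make_regressors(nt = 50, nf = 3, seed = 29)
  o <- orthogonalize_features(x)
  vs <- make_series(shape = c(4, 4, 4), nt = 5, seed = 30)
  vals <- array(rnorm(64), dim = c(4, 4, 4))
  tm <- stat_map(vals, "t", vs$affine, feature = "f1")
  rep_same <- compare_orthogonalization(
    list(f1 = tm), list(f1 = tm), x, o$residuals
  )
  expect_equal(rep_same$spatial_r, 1)
  # a feature orthogonal to all others keeps its regressor: temporal r = 1
  xq <- qr.Q(qr(cbind(1, make_regressors(nt = 50, nf = 3, seed = 31))))[, 2:4]
  colnames(xq) <- paste0("f", 1:3)
  oq <- orthogonalize_features(xq)
  rep_orth <- compare_orthogonalization(
    list(f1 = tm), list(f1 = tm), xq, oq$residuals
  )
  expect_equal(rep_orth$temporal_r, 1, tolerance = 1e-6)
})
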