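test_that("noiseless data are fit exactly", {
  nt <- 50
  x <- make_regressors(nt = nt, nf = 3, seed = 40)
  beta <- c(2, -1, 0.5)
  vs <- make_series(shape = c(3, 3, 2), nt = nt, seed = 41)
  vs$data <- array(rep(drop(x %*% beta), each = 18), dim = c(3, 3, 2, nt))
  des <- build_design_matrix(x, 2.112, highpass_cutoff_s = 1e6, hrf_mode = "none")
  fit <- fit_glm(vs, des, ar1 = ar1_model(0))
  for (i in 1:3) {
    expect_equal(in_mask_values(fit$beta[[i]]), rep(beta[i], 18), tolerance = 1e-10)
  }
})

test_that("rho = 0 whitening reduces to ordinary least squares", {
  nt <- 40
  x <- make_regressors(nt = nt, nf = 2, seed = 42)
  vs <- make_series(shape = c(2, 2, 2), nt = nt, seed = 43)
  des <- build_design_matrix(x, 2.112, highpass_cutoff_s = 1e6, hrf_mode = "none")
  fit <- fit_glm(vs, des, ar1 = ar1_model(0))
  y1 <- vs$data[1, 1, 1, ]
  ols <- lm(y1 ~ x)
  expect_equal(fit$beta[["f1"]]$values[1, 1, 1], unname(coef(ols)["xf1"]),
               tolerance = 1e-10)
  expect_equal(fit$t[["f1"]]$values[1, 1, 1],
               unname(summary(ols)$coefficients["xf1", "t value"]),
               tolerance = 1e-8)
})

test_that("prewhitened OLS equals dense GLS with the full AR(1) covariance", {
  for (case in list(c(nt = 20, rho = 0.4), c(nt = 35, rho = 0.6),
                    c(nt = 50, rho = 0.25))) {
    nt <- case[["nt"]]
    rho <- case[["rho"]]
    x <- cbind(make_regressors(nt = nt, nf = 2, seed = nt), `(i)` = 1)
    withr::with_seed(nt + 1, y <- matrix(rnorm(nt * 4), nt, 4))
    # dense GLS oracle with unit-marginal AR(1) covariance
    sigma <- rho^abs(outer(seq_len(nt), seq_len(nt), "-"))
    si <- solve(sigma)
    gls_beta <- solve(t(x) %*% si %*% x, t(x) %*% si %*% y)
    gls_cov <- solve(t(x) %*% si %*% x)
    df <- nt - ncol(x)
    res <- y - x %*% gls_beta
    gls_se <- sqrt(outer(diag(gls_cov),
                         colSums(res * (si %*% res)) / df))
    xw <- ar1_whiten(x, rho)
    yw <- ar1_whiten(y, rho)
    fit <- socmap:::solve_ols(xw, yw)
    expect_lt(max(abs(fit$beta - gls_beta)), 1e-8)
    expect_lt(max(abs(fit$se - gls_se)), 1e-8)
  }
})

test_that("pooled AR(1) estimation recovers the noise coefficient", {
  withr::with_seed(50, {
    wn <- matrix(rnorm(768 * 500), 768, 500)
  })
  expect_lt(abs(estimate_ar1(wn)$rho), 0.05)
  withr::with_seed(51, {
    innov <- matrix(rnorm(818 * 300), 818, 300)
    ar <- stats::filter(innov, 0.4, method = "recursive")[51:818, ]
  })
  est <- estimate_ar1(ar)
  expect_lt(abs(est$rho - 0.4), 0.05)
  expect_error(estimate_ar1(matrix(2, 50, 3)), class = "socmap_error_degenerate")
  expect_error(ar1_whiten(1:5, 1.2), class = "socmap_error_stability")
})

test_that("per-feature fitting equals separate single-feature GLMs", {
  nt <- 60
  x <- make_regressors(nt = nt, nf = 4, seed = 52)
  vs <- make_series(shape = c(3, 3, 3), nt = nt, seed = 53)
  des <- build_design_matrix(x, 2.112, highpass_cutoff_s = 120, hrf_mode = "none")
  fast <- fit_first_level(vs, des, mode = "per_feature", ar1 = ar1_model(0.3))
  for (f in colnames(x)) {
    one <- build_design_matrix(x[, f, drop = FALSE], 2.112,
                               highpass_cutoff_s = 120, hrf_mode = "none")
    naive <- fit_glm(vs, one, ar1 = ar1_model(0.3))
    expect_equal(in_mask_values(fast$beta[[f]]), in_mask_values(naive$beta[[f]]),
                 tolerance = 1e-10)
    expect_equal(in_mask_values(fast$t[[f]]), in_mask_values(naive$t[[f]]),
                 tolerance = 1e-8)
    expect_equal(fast$df, naive$df)
  }
})

test_that("social vs non-social contrast is the mean difference of betas", {
  vs <- make_series(shape = c(3, 3, 3), nt = 4, seed = 54)
  mk <- function(v, f) stat_map(array(v, dim = c(3, 3, 3)), "beta", vs$affine,
                                feature = f)
  all_feats <- default_features()$feature
  maps <- lapply(all_feats, function(f) mk(1, f))
  names(maps) <- all_feats
  same <- social_vs_nonsocial_contrast(maps)
  expect_true(all(in_mask_values(same) == 0))
  maps2 <- maps
  for (f in social_features()) maps2[[f]] <- mk(1, f)
  for (f in nonsocial_features()) maps2[[f]] <- mk(0, f)
  expect_true(all(in_mask_values(social_vs_nonsocial_contrast(maps2)) == 1))
  withr::with_seed(55, vals <- lapply(all_feats, function(f) array(rnorm(27), dim = c(3, 3, 3))))
  names(vals) <- all_feats
  maps3 <- purrr::imap(vals, function(v, f) stat_map(v, "beta", vs$affine, feature = f))
  got <- social_vs_nonsocial_contrast(maps3)
  oracle <- Reduce(`+`, vals[social_features()]) / 8 -
    Reduce(`+`, vals[nonsocial_features()]) / 6
  expect_equal(got$values, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(social_vs_nonsocial_contrast(maps3[-1]),
               class = "socmap_error_completeness")
})

test_that("betas are invariant to adding drift-span components to the data", {
  nt <- 64
  x <- make_regressors(nt = nt, nf = 2, seed = 56)
  des <- build_design_matrix(x, 2.112, highpass_cutoff_s = 60, hrf_mode = "none")
  vs <- make_series(shape = c(2, 2, 2), nt = nt, seed = 57)
  fit0 <- fit_glm(vs, des, ar1 = ar1_model(0))
  drifted <- vs
  drift_comp <- drop(des$drift %*% seq_len(ncol(des$drift)))
  drifted$data <- vs$data + array(rep(drift_comp, each = 8), dim = c(2, 2, 2, nt))
  fit1 <- fit_glm(drifted, des, ar1 = ar1_model(0))
  expect_equal(in_mask_values(fit1$beta[["f1"]]), in_mask_values(fit0$beta[["f1"]]),
               tolerance = 1e-8)
})
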