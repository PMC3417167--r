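test_that("generated ratings stay on the 1-5 scale with consistent lengths", {
  rs <- generate_ratings(n_clips = 8, seed = 60)
  expect_true(all(rs$ratings$value >= 1 & rs$ratings$value <= 5))
  expect_true(all(rs$latent$value >= 1 & rs$latent$value <= 5))
  lens <- rs$ratings |>
    dplyr::count(.data$clip_id, .data$feature, .data$rater) |>
    dplyr::left_join(rs$clips, by = "clip_id")
  expect_true(all(lens$n == lens$n_samples))
  expect_setequal(rs$presentation_order, rs$clips$clip_id)
  expect_error(
    generate_ratings(n_clips = 2, corr_target = matrix(c(1, 2, 2, 1), 2), seed = 1),
    class = "socmap_error_validation"
  )
})

test_that("zero rater noise makes the raters identical; reliability rises as
           noise falls", {
  rs0 <- generate_ratings(n_clips = 4, rater_noise_sd = 0, seed = 61)
  wide <- tidyr::pivot_wider(rs0$ratings, names_from = "rater",
                             values_from = "value")
  expect_equal(wide$rater_1, wide$rater_2)

  rels <- vapply(c(1.2, 0.5, 0.1), function(s) {
    rs <- generate_ratings(n_clips = 12, rater_noise_sd = s, seed = 62)
    attr(interrater_reliability(rs$ratings), "mean_r")
  }, numeric(1))
  expect_true(all(diff(rels) > 0))
  expect_gt(rels[3], 0.95)
})

test_that("an identity correlation target yields near-independent features", {
  rs <- generate_ratings(n_clips = 40, corr_target = diag(14), seed = 63)
  reg <- ratings_to_regressors(rs, 2.112)
  expect_lt(mean_abs_offdiag(feature_correlation_matrix(reg)), 0.12)
})

test_that("noiseless BOLD recovers the planted betas exactly", {
  x <- make_regressors(nt = 30, nf = 14, seed = 64,
                       names = default_features()$feature)
  des <- build_design_matrix(x, 2.112, highpass_cutoff_s = 1e6, hrf_mode = "none")
  truth <- ground_truth_regions(shape = c(10, 10, 10), voxel_mm = 10,
                                region_radius_mm = 10)
  bold <- generate_bold(des, truth, n_subjects = 1, noise_sd = 1e-8,
                        ar1_rho = 0, subject_sd = 0, seed = 65)
  fit <- fit_glm(bold$series[[1]], des, ar1 = ar1_model(0))
  hub <- which(truth$region_labels == 1)
  for (f in social_features()) {
    expect_equal(unname(fit$beta[[f]]$values[hub]),
                 rep(truth$amplitude, length(hub)), tolerance = 1e-6)
  }
  for (f in nonsocial_features()) {
    expect_lt(max(abs(fit$beta[[f]]$values[hub])), 1e-6)
  }
})

test_that("the AR(1) noise generator hits its coefficient", {
  x <- make_regressors(nt = 768, nf = 14, seed = 66,
                       names = default_features()$feature)
  des <- build_design_matrix(x, 2.112, highpass_cutoff_s = 1e6, hrf_mode = "none")
  truth <- ground_truth_regions(shape = c(10, 10, 10), voxel_mm = 10)
  bold <- generate_bold(des, truth, n_subjects = 1, noise_sd = 1,
                        ar1_rho = 0.4, subject_sd = 0, seed = 67)
  # pure-noise voxels: in-mask, outside every planted region
  vs <- bold$series[[1]]
  idx <- which(vs$mask & bold$truth$region_labels == 0)[1:500]
  noise_mat <- t(matrix(vs$data, 1000, 768)[idx, ])
  est <- estimate_ar1(noise_mat)
  expect_lt(abs(est$rho - 0.4), 0.02) # bias bound at T = 768, 500 voxels
  expect_error(
    generate_bold(des, truth, n_subjects = 1, ar1_rho = 1.01, seed = 1),
    class = "socmap_error_stability"
  )
})

test_that("the hub responds to all social and no non-social features", {
  truth <- ground_truth_regions()
  hub <- which(truth$region_labels == 1)
  bt <- matrix(truth$beta_true, nrow = prod(truth$shape))
  colnames(bt) <- dimnames(truth$beta_true)[[4]]
  expect_true(all(bt[hub, social_features()] > 0))
  expect_true(all(bt[hub, nonsocial_features()] <= 0))
  # specialized regions respond to strict subsets of the social features
  for (i in which(truth$regions$type == "specialized")) {
    idx <- which(truth$region_labels == i)
    on <- colnames(bt)[colSums(bt[idx, , drop = FALSE] > 0) > 0]
    expect_true(length(intersect(on, social_features())) < 8)
  }
})

test_that("planted-partition graphs respect their module structure", {
  g0 <- planted_partition_graph(12, 3, p_in = 0.9, p_out = 0, seed = 70)
  # with p_out = 0, connected components equal planted modules
  reach <- function(w, i) {
    seen <- i
    repeat {
      nxt <- unique(c(seen, which(colSums(w[seen, , drop = FALSE] > 0) > 0)))
      if (length(nxt) == length(seen)) return(sort(seen))
      seen <- nxt
    }
  }
  for (m in unique(g0$labels)) {
    members <- which(g0$labels == m)
    expect_equal(reach(g0$weights, members[1]), members)
  }
  g1 <- planted_partition_graph(6, 1, p_in = 0.8, p_out = 0.1, seed = 71)
  expect_true(all(g1$labels == 1))
  expect_error(planted_partition_graph(10, 2, p_in = 0.1, p_out = 0.5),
               class = "socmap_error_validation")
})
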