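test_that("rater averaging is the element-wise mean", {
  a <- matrix(c(1, 3), ncol = 1)
  b <- matrix(c(3, 5), ncol = 1)
  tbl <- make_rating_tbl(list(c1 = list(a = a, b = b)))
  out <- average_raters(tbl)
  expect_equal(out$value, c(2, 4))

  withr::with_seed(10, {
    ra <- matrix(runif(60, 1, 5), 20, 3)
    rb <- matrix(runif(60, 1, 5), 20, 3)
  })
  tbl2 <- make_rating_tbl(list(c1 = list(a = ra, b = rb)))
  out2 <- average_raters(tbl2)
  oracle <- (ra + rb) / 2
  expect_equal(
    matrix(out2$value[order(match(out2$feature, paste0("f", 1:3)), out2$sample_index)],
           20, 3),
    oracle, ignore_attr = TRUE
  )
  # identical raters pass through unchanged
  tbl3 <- make_rating_tbl(list(c1 = list(a = ra, b = ra)))
  expect_equal(sort(average_raters(tbl3)$value), sort(as.vector(ra)))
  # unequal track lengths are alignment errors
  tbl4 <- dplyr::filter(tbl2, !(rater == "b" & sample_index == 20))
  expect_error(average_raters(tbl4), class = "socmap_error_alignment")
})

test_that("clip concatenation respects presentation order block by block", {
  withr::with_seed(11, {
    c1 <- matrix(runif(100, 1, 5), 50, 2)
    c2 <- matrix(runif(100, 1, 5), 50, 2)
  })
  tracks <- dplyr::bind_rows(
    make_rating_tbl(list(clip_a = list(a = c1))),
    make_rating_tbl(list(clip_b = list(a = c2)))
  ) |> dplyr::select(-"rater")
  one <- concatenate_clips(dplyr::filter(tracks, clip_id == "clip_a"), "clip_a")
  expect_equal(dplyr::filter(one, feature == "f1")$value, c1[, 1])

  both <- concatenate_clips(tracks, c("clip_b", "clip_a"))
  f1 <- dplyr::filter(both, feature == "f1")
  expect_equal(nrow(f1), 100)
  expect_equal(f1$sample_index, 1:100)
  expect_equal(f1$value, c(c2[, 1], c1[, 1])) # blockwise oracle
  expect_error(concatenate_clips(tracks, c("clip_a", "clip_missing")),
               class = "socmap_error_completeness")
})

test_that("TR down-sampling matches an explicit window oracle", {
  # constant track stays constant
  const <- tibble::tibble(feature = "f1", sample_index = 1:50, value = 4)
  expect_true(all(downsample_to_tr(const, 5, 2.112)$value == 4))

  # 5 Hz ramp against brute-force windowing
  n <- 83 # 16.6 s at 5 Hz
  ramp <- tibble::tibble(feature = "f1", sample_index = 1:n, value = 0:(n - 1))
  out <- downsample_to_tr(ramp, 5, 2.112)
  expect_equal(nrow(out), 7) # floor(16.6 / 2.112)
  oracle <- vapply(seq_len(7), function(k) {
    t_center <- (seq_len(n) - 0.5) / 5
    mean(ramp$value[t_center >= (k - 1) * 2.112 & t_center < k * 2.112])
  }, numeric(1))
  expect_equal(out$value, oracle)

  # commutes with affine transforms of the values
  shifted <- dplyr::mutate(ramp, value = 3 * value + 2)
  expect_equal(downsample_to_tr(shifted, 5, 2.112)$value, 3 * out$value + 2)

  expect_error(downsample_to_tr(ramp, 0.4, 2), class = "socmap_error_validation")
})

test_that("averaging and concatenation commute", {
  withr::with_seed(12, {
    clips <- list(
      ca = list(r1 = matrix(runif(40, 1, 5), 20, 2),
                r2 = matrix(runif(40, 1, 5), 20, 2)),
      cb = list(r1 = matrix(runif(30, 1, 5), 15, 2),
                r2 = matrix(runif(30, 1, 5), 15, 2))
    )
  })
  tbl <- make_rating_tbl(clips)
  ord <- c("cb", "ca")
  avg_then_cat <- concatenate_clips(average_raters(tbl), ord)
  # concatenate each rater separately, then average the concatenated tracks
  cat_r1 <- concatenate_clips(
    dplyr::select(dplyr::filter(tbl, rater == "r1"), -"rater"), ord
  )
  cat_r2 <- concatenate_clips(
    dplyr::select(dplyr::filter(tbl, rater == "r2"), -"rater"), ord
  )
  cat_then_avg <- dplyr::mutate(cat_r1, value = (cat_r1$value + cat_r2$value) / 2)
  expect_equal(avg_then_cat$value, cat_then_avg$value)
})

test_that("inter-rater reliability handles exact, reflected and noisy raters", {
  withr::with_seed(13, a <- matrix(runif(80, 1.5, 4.5), 40, 2))
  same <- make_rating_tbl(list(c1 = list(r1 = a, r2 = a)))
  rel <- interrater_reliability(same)
  expect_equal(rel$r, c(1, 1))
  expect_equal(attr(rel, "mean_r"), 1)

  flipped <- make_rating_tbl(list(c1 = list(r1 = a, r2 = -a + 6)))
  expect_equal(interrater_reliability(flipped)$r, c(-1, -1))

  # closed-form attenuation: r = 1 / (1 + sd^2) for additive latent noise
  withr::with_seed(14, {
    latent <- matrix(rnorm(6000), 3000, 2)
    nsd <- 0.6
    r1 <- latent + nsd * matrix(rnorm(6000), 3000, 2)
    r2 <- latent + nsd * matrix(rnorm(6000), 3000, 2)
  })
  # map linearly into the rating scale (correlation-invariant)
  sc <- function(m) 3 + 0.5 * m / max(abs(m))
  noisy <- make_rating_tbl(list(c1 = list(r1 = sc(r1), r2 = sc(r2))))
  rel2 <- interrater_reliability(noisy)
  expect_equal(attr(rel2, "mean_r"), 1 / (1 + nsd^2), tolerance = 0.05)

  flat <- make_rating_tbl(list(c1 = list(r1 = a, r2 = matrix(3, 40, 2))))
  expect_error(interrater_reliability(flat),
               class = "socmap_error_undefined_correlation")
})

test_that("feature correlation matrix is symmetric, unit-diagonal and PSD", {
  m <- cbind(f1 = sin(seq_len(64) / 3), f2 = cos(seq_len(64) / 3))
  fc <- feature_correlation_matrix(m)
  expect_lt(abs(fc[1, 2]), 0.06) # near-orthogonal regressors
  dup <- cbind(m, f3 = m[, 1])
  fc2 <- feature_correlation_matrix(dup)
  expect_equal(fc2["f1", "f3"], 1)
  withr::with_seed(15, r <- matrix(rnorm(300), 100, 3))
  colnames(r) <- paste0("f", 1:3)
  fc3 <- feature_correlation_matrix(r)
  expect_equal(fc3, t(fc3))
  expect_equal(unname(diag(fc3)), rep(1, 3))
  expect_gte(min(eigen(fc3, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(feature_correlation_matrix(cbind(f1 = rep(2, 10), f2 = rnorm(10))),
               class = "socmap_error_undefined_correlation")
})
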