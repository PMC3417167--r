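test_that("subject connectivity matches the covariance-formula oracle", {
  withr::with_seed(100, m <- matrix(rnorm(200 * 4), 200, 4))
  colnames(m) <- paste0("r", 1:4)
  got <- subject_connectivity(m)
  oracle <- outer(1:4, 1:4, Vectorize(function(i, j) {
    xi <- m[, i] - mean(m[, i])
    xj <- m[, j] - mean(m[, j])
    sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }))
  expect_equal(unname(got), oracle, tolerance = 1e-12)
  expect_equal(unname(diag(got)), rep(1, 4))
  dup <- cbind(m[, 1], m[, 1])
  expect_equal(subject_connectivity(dup)[1, 2], 1)
  expect_error(subject_connectivity(cbind(m[, 1], rep(1, 200))),
               class = "socmap_error_undefined_correlation")
  expect_error(subject_connectivity(m[1:2, ]), class = "socmap_error_validation")
})

test_that("Fisher-z group averaging matches the closed form", {
  r1 <- matrix(c(1, 0.5, 0.5, 1), 2)
  r2 <- matrix(c(1, 0.8, 0.8, 1), 2)
  got <- group_mean_connectivity(list(r1, r2))
  expect_equal(got[1, 2], tanh(mean(c(atanh(0.5), atanh(0.8)))), tolerance = 1e-10)
  expect_equal(got[1, 2], 0.6777, tolerance = 1e-3)
  # identical subjects are a fixed point; antisymmetric pairs cancel
  expect_equal(group_mean_connectivity(list(r1, r1)), r1, tolerance = 1e-12)
  rneg <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(group_mean_connectivity(list(r1, rneg))[1, 2], 0)
  rsat <- matrix(c(1, 1, 1, 1), 2)
  expect_error(group_mean_connectivity(list(rsat)),
               class = "socmap_error_saturation")
})

test_that("circular shifts rotate, invert, and preserve structure", {
  withr::with_seed(101, x <- as.numeric(arima.sim(list(ar = 0.6), 400)))
  k <- 37
  shifted <- circular_shift(x, k)
  expect_equal(sort(shifted), sort(x))
  expect_equal(circular_shift(shifted, length(x) - k), x)
  lag1 <- function(v) cor(v[-1], v[-length(v)])
  expect_lt(abs(lag1(shifted) - lag1(x)), 2 / length(x) + 0.05)
  expect_error(circular_shift(x, 0), class = "socmap_error_validation")
  expect_error(circular_shift(x, 400), class = "socmap_error_validation")
  expect_error(circular_shift(x, 5, min_shift = 10), class = "socmap_error_validation")
})

test_that("the FFT cross-correlation stack equals direct shifted correlations", {
  withr::with_seed(102, z <- matrix(rnorm(60 * 3), 60, 3))
  zs <- socmap:::standardize_cols(z)
  stack <- socmap:::crosscor_stack(zs)
  for (g in 1:3) for (j in 1:3) for (k in c(1, 7, 30, 59)) {
    expect_equal(stack[k + 1, g, j],
                 cor(circular_shift(zs[, g], k), zs[, j]),
                 tolerance = 1e-10)
  }
})

test_that("permutation thresholds are monotone in the permutation count and
           bound true-null correlations", {
  withr::with_seed(103, ser <- lapply(1:6, function(s) matrix(rnorm(300 * 5), 300, 5)))
  small <- permutation_threshold(ser, n_perm = 100, min_shift = 10, seed = 5)
  big <- permutation_threshold(ser, n_perm = 1000, min_shift = 10, seed = 5)
  expect_gte(big$threshold, small$threshold) # nested streams: superset max
  # observed null connectivity falls below the permutation threshold
  mean_r <- group_mean_connectivity(lapply(ser, subject_connectivity))
  expect_lt(max(abs(mean_r[lower.tri(mean_r)])), big$threshold)
  expect_error(permutation_threshold(ser, n_perm = 0, seed = 1),
               class = "socmap_error_validation")
  expect_error(permutation_threshold(lapply(ser, function(m) m[1:15, ]),
                                     n_perm = 10, min_shift = 10, seed = 1),
               class = "socmap_error_validation")
  # subject-pooled variant yields a larger (un-averaged) threshold
  pooled <- permutation_threshold(ser, n_perm = 100, min_shift = 10, seed = 5,
                                  pooling = "subject_pool")
  expect_gt(pooled$threshold, small$threshold)
})

test_that("graph construction thresholds edges exactly", {
  withr::with_seed(104, {
    z <- matrix(rnorm(25), 5)
    r <- cov2cor(crossprod(z) + diag(5))
  })
  colnames(r) <- rownames(r) <- paste0("n", 1:5)
  expect_equal(nrow(build_graph(r, max(abs(r[lower.tri(r)])) + 0.01)$edges), 0)
  expect_equal(nrow(build_graph(r, 0)$edges), choose(5, 2))
  thr <- 0.3
  g <- build_graph(r, thr)
  oracle <- which(upper.tri(r) & abs(r) > thr, arr.ind = TRUE)
  expect_equal(nrow(g$edges), nrow(oracle))
  for (k in seq_len(nrow(oracle))) {
    expect_true(any(g$edges$node_a == paste0("n", oracle[k, 1]) &
                      g$edges$node_b == paste0("n", oracle[k, 2])))
  }
  expect_equal(sum(g$degree$degree), 2 * nrow(g$edges))
  # edge list round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  expect_equal(readr::read_tsv(path, show_col_types = FALSE)$mean_r, g$edges$mean_r)
})

test_that("the map equation matches closed-form entropies", {
  # single-module L is the entropy of visit rates: 4-node star
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- w[2:4, 1] <- 1
  expect_equal(map_equation(w, rep(1, 4)),
               -(0.5 * log2(0.5) + 3 * (1 / 6) * log2(1 / 6)), tolerance = 1e-10)
  expect_equal(map_equation(w, rep(1, 4)), 1.7925, tolerance = 1e-4)
  # two cliques with a weak bridge: 2-module coding is shorter
  w2 <- matrix(0, 6, 6)
  w2[1:3, 1:3] <- 1; w2[4:6, 4:6] <- 1; diag(w2) <- 0
  w2[3, 4] <- w2[4, 3] <- 0.05
  expect_lt(map_equation(w2, rep(1:2, each = 3)), map_equation(w2, rep(1, 6)))
  # module labels are arbitrary
  expect_equal(map_equation(w2, c(9, 9, 9, 4, 4, 4)),
               map_equation(w2, rep(1:2, each = 3)))
  expect_error(map_equation(w2, c(1, 1, 1)), class = "socmap_error_validation")
})

test_that("community detection recovers structure and is reproducible", {
  # disconnected cliques: exact recovery with full consensus
  w <- matrix(0, 7, 7)
  w[1:3, 1:3] <- 1; w[4:7, 4:7] <- 1; diag(w) <- 0
  cp <- detect_communities(w, n_restarts = 20, seed = 7)
  expect_equal(cp$assignment$module, rep(1:2, c(3, 4)))
  expect_equal(cp$modal_fraction, 1)
  # arg-min property: returned L no worse than any restart or one module
  g <- planted_partition_graph(14, 4, 0.9, 0.05, sizes = c(4, 4, 3, 3), seed = 8)
  cp2 <- detect_communities(g$weights, n_restarts = 50, seed = 9)
  expect_true(all(cp2$description_length <= cp2$restart_lengths + 1e-12))
  expect_lte(cp2$description_length, map_equation(g$weights, rep(1, 14)))
  # planted recovery, cross-checked against an independent implementation
  expect_equal(socmap:::canonical_assignment(cp2$assignment$module),
               socmap:::canonical_assignment(g$labels))
  skip_if_not_installed("igraph")
  ig <- igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                            weighted = TRUE)
  im <- igraph::membership(igraph::cluster_infomap(ig))
  expect_equal(socmap:::canonical_assignment(as.integer(im)),
               socmap:::canonical_assignment(cp2$assignment$module))
  # reproducibility: same seed, same partition
  cp3 <- detect_communities(g$weights, n_restarts = 50, seed = 9)
  expect_identical(cp2$assignment, cp3$assignment)
  expect_identical(cp2$description_length, cp3$description_length)
})
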