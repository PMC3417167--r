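#' Subject-level ROI connectivity matrix
#'
#' Pearson correlations between the mean ROI time series of one subject.
#'
#' @param roi_series Time x ROI matrix (>= 3 samples).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
subject_connectivity <- function(roi_series) {
  m <- as.matrix(roi_series)
  if (nrow(m) < 3) stop_socmap("need at least 3 samples", "validation")
  if (any(apply(m, 2, sd) == 0)) {
    stop_socmap("zero-variance ROI series: correlation undefined",
                "undefined_correlation")
  }
  cor(m)
}

#' Fisher-z averaged group connectivity
#'
#' Entrywise `tanh(mean(atanh(r)))` across subjects: the Fisher z-transform
#' is applied to each correlation, averaged over subjects, and the mean is
#' inverse transformed.
#'
#' @param subject_r List of subject correlation matrices.
#' @return Group mean correlation matrix.
#' @export
group_mean_connectivity <- function(subject_r) {
  for (r in subject_r) {
    off <- r[lower.tri(r)]
    if (any(abs(off) >= 1)) {
      stop_socmap("|r| = 1 off-diagonal: Fisher transform saturates", "saturation")
    }
  }
  z <- Reduce(`+`, lapply(subject_r, atanh)) / length(subject_r)
  out <- tanh(z)
  diag(out) <- 1
  out
}

#' Circular shift of a time series
#'
#' Rotates the series by `k` samples (value at time t moves to t + k,
#' wrapping around); the multiset of values, the marginal distribution, and
#' (up to wrap effects) the autocorrelation are preserved while
#' cross-correlations with other series are destroyed.
#'
#' @param x Numeric vector.
#' @param k Shift in samples, `min_shift <= k <= length(x) - min_shift`.
#' @param min_shift Minimum allowed shift (default 1 rules out the identity).
#' @return The rotated vector.
#' @export
circular_shift <- function(x, k, min_shift = 1) {
  n <- length(x)
  if (k < min_shift || k > n - min_shift) {
    stop_socmap(
      sprintf("shift k = %d outside [%d, %d]", k, min_shift, n - min_shift),
      "validation"
    )
  }
  x[((seq_len(n) - 1 - k) %% n) + 1]
}

# Circular cross-correlation stack for one subject: element [lag + 1, g, j]
# is cor(circular_shift(series g, lag), series j), computed via FFT on
# standardized columns.
crosscor_stack <- function(z) {
  n <- nrow(z)
  r <- ncol(z)
  fz <- stats::mvfft(z)
  out <- array(NA_real_, dim = c(n, r, r))
  for (g in seq_len(r)) {
    cc <- Re(stats::mvfft(Conj(fz[, g]) * fz, inverse = TRUE)) / n
    out[, g, ] <- cc / (n - 1)
  }
  out
}

standardize_cols <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  sweep(m, 2, apply(m, 2, sd), "/")
}

#' Circular-shift permutation threshold for group connectivity
#'
#' Builds the null distribution of the group-level connectivity statistic:
#' in each permutation, every subject independently gets a random seed ROI
#' whose series is circularly shifted by a uniform `k` in
#' `[min_shift, T - min_shift]` and correlated with all other ROIs; the
#' seed-to-target correlations are Fisher-z averaged across subjects
#' position-wise, and the threshold is the maximum `|r|` observed anywhere in
#' the pooled null (`pooling = "group_mean"`, matching the statistic being
#' thresholded). `pooling = "subject_pool"` instead pools all subject-level
#' permuted correlations without averaging.
#'
#' @param roi_series One time x ROI matrix, or a list of them (one per
#'   subject, same dimensions).
#' @param n_perm Number of permutations (>= 1).
#' @param min_shift Minimum circular shift in samples.
#' @param seed RNG seed.
#' @param pooling `"group_mean"` or `"subject_pool"`.
#' @return List: `threshold`, `null_quantiles`, `n_perm`, `min_shift`,
#'   `pooling`, `n_subjects`, `n_rois`.
#' @export
permutation_threshold <- function(roi_series, n_perm = 1e4, min_shift = 10,
                                  seed = NULL,
                                  pooling = c("group_mean", "subject_pool")) {
  pooling <- match.arg(pooling)
  if (n_perm < 1) stop_socmap("n_perm must be at least 1", "validation")
  if (is.matrix(roi_series)) roi_series <- list(roi_series)
  n_subj <- length(roi_series)
  nt <- nrow(roi_series[[1]])
  nr <- ncol(roi_series[[1]])
  if (nr < 2) stop_socmap("need at least 2 ROIs", "validation")
  if (nt < 2 * min_shift) {
    stop_socmap("series length must be at least 2 * min_shift", "validation")
  }
  stacks <- lapply(roi_series, function(m) crosscor_stack(standardize_cols(as.matrix(m))))
  # separate seed/lag streams, drawn permutation-major, so that the first k
  # permutations of a longer run coincide with a k-permutation run
  seeds <- with_seed(child_seed(seed, 1), {
    t(matrix(sample.int(nr, n_subj * n_perm, replace = TRUE), n_subj, n_perm))
  })
  lags <- with_seed(child_seed(seed, 2), {
    t(matrix(sample(seq.int(min_shift, nt - min_shift), n_subj * n_perm,
                    replace = TRUE), n_subj, n_perm))
  })
  local({
    if (pooling == "group_mean") {
      z_acc <- matrix(0, n_perm, nr)
      z_n <- matrix(0L, n_perm, nr)
      for (s in seq_len(n_subj)) {
        v <- matrix(NA_real_, n_perm, nr)
        for (j in seq_len(nr)) {
          v[, j] <- stacks[[s]][cbind(lags[, s] + 1L, seeds[, s], j)]
        }
        v[cbind(seq_len(n_perm), seeds[, s])] <- NA_real_
        contrib <- !is.na(v)
        zv <- atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12))
        zv[!contrib] <- 0
        z_acc <- z_acc + zv
        z_n <- z_n + contrib
      }
      pooled <- tanh(z_acc / pmax(z_n, 1L))
      pooled[z_n == 0] <- NA_real_
      null_abs <- abs(pooled[!is.na(pooled)])
    } else {
      vals <- lapply(seq_len(n_subj), function(s) {
        v <- matrix(NA_real_, n_perm, nr)
        for (j in seq_len(nr)) {
          v[, j] <- stacks[[s]][cbind(lags[, s] + 1L, seeds[, s], j)]
        }
        v[cbind(seq_len(n_perm), seeds[, s])] <- NA_real_
        v
      })
      null_abs <- abs(unlist(vals))
      null_abs <- null_abs[!is.na(null_abs)]
    }
    list(
      threshold = max(null_abs),
      null_quantiles = stats::quantile(null_abs, c(0.5, 0.9, 0.99, 1)),
      n_perm = n_perm, min_shift = min_shift, pooling = pooling,
      n_subjects = n_subj, n_rois = nr
    )
  })
}

#' Threshold the group connectivity matrix into a graph
#'
#' An edge links two ROIs iff `|mean_r| > threshold` (strict: the threshold
#' is the maximum of a pure-null distribution).
#'
#' @param mean_r Group mean correlation matrix (symmetric).
#' @param threshold Permutation threshold (>= 0).
#' @param nodes Optional node names (default: matrix dimnames or n1..).
#' @return A `connectivity_graph`: `nodes`, `mean_r`, `threshold`, `edges`
#'   tibble (`node_a`, `node_b`, `mean_r`), and `degree` tibble.
#' @export
build_graph <- function(mean_r, threshold, nodes = NULL) {
  if (max(abs(mean_r - t(mean_r))) > 1e-10) {
    stop_socmap("mean_r must be symmetric", "validation")
  }
  n <- nrow(mean_r)
  if (is.null(nodes)) nodes <- colnames(mean_r) %||% paste0("n", seq_len(n))
  idx <- which(upper.tri(mean_r) & abs(mean_r) > threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    node_a = nodes[idx[, 1]],
    node_b = nodes[idx[, 2]],
    mean_r = mean_r[idx]
  )
  deg <- tibble::tibble(
    node = nodes,
    degree = vapply(seq_len(n), function(i) {
      sum(abs(mean_r[i, -i]) > threshold)
    }, integer(1))
  )
  structure(
    list(nodes = nodes, mean_r = mean_r, threshold = threshold,
         edges = edges, degree = deg),
    class = "connectivity_graph"
  )
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> %d nodes, %d edges (|r| > %.4f)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' @export
tidy.connectivity_graph <- function(x, ...) x$edges

#' @export
glance.connectivity_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes), n_edges = nrow(x$edges),
    threshold = x$threshold, mean_degree = mean(x$degree$degree)
  )
}

#' Write a graph as a weighted edge list
#'
#' @param graph A `connectivity_graph`.
#' @param path TSV path (columns `node_a`, `node_b`, `mean_r`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  readr::write_tsv(graph$edges, path, progress = FALSE)
  invisible(path)
}

# Weighted adjacency matrix of a connectivity graph (|r| edge weights).
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  w <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0) {
    ia <- match(graph$edges$node_a, graph$nodes)
    ib <- match(graph$edges$node_b, graph$nodes)
    w[cbind(ia, ib)] <- abs(graph$edges$mean_r)
    w[cbind(ib, ia)] <- abs(graph$edges$mean_r)
  }
  w
}
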