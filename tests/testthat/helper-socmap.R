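# Shared fixtures, built in code at test time.

# Small volume series with iid normal data on an isotropic grid.
make_series <- function(shape = c(6, 6, 6), nt = 40, voxel_mm = 2,
                        subject_id = "test", seed = 1, mask = NULL) {
  withr::with_seed(seed, {
    affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
    affine[1:3, 4] <- -voxel_mm * (shape - 1) / 2
    volume_series(
      data = array(rnorm(prod(shape) * nt), dim = c(shape, nt)),
      affine = affine, tr_s = 2.112, mask = mask, subject_id = subject_id
    )
  })
}

# Smooth random regressors on the acquisition grid (time x feature matrix).
make_regressors <- function(nt = 40, nf = 3, seed = 2,
                            names = paste0("f", seq_len(nf))) {
  withr::with_seed(seed, {
    m <- vapply(seq_len(nf), function(i) {
      as.numeric(stats::filter(rnorm(nt + 10), rep(1 / 4, 4), sides = 1))[11:(nt + 10)]
    }, numeric(nt))
    colnames(m) <- names
    m
  })
}

# Long rating tibble for two raters from a pair of per-clip value matrices.
make_rating_tbl <- function(values_by_clip, features = NULL) {
  purrr::imap_dfr(values_by_clip, function(clip, clip_id) {
    purrr::imap_dfr(clip, function(track, rater) {
      nf <- ncol(track)
      feats <- features %||% paste0("f", seq_len(nf))
      tibble::tibble(
        clip_id = clip_id,
        feature = rep(feats, each = nrow(track)),
        rater = rater,
        sample_index = rep(seq_len(nrow(track)), nf),
        value = as.vector(track)
      )
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force Benjamini-Hochberg oracle.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) {
    list(significant = rep(FALSE, m), p_star = 0)
  } else {
    p_star <- ps[max(ok)]
    list(significant = p <= p_star, p_star = p_star)
  }
}

# Exhaustive lattice-enumeration oracle for sphere voxel counts on an
# isotropic grid with the center on a voxel center.
sphere_count_oracle <- function(radius_mm, voxel_mm) {
  k <- ceiling(radius_mm / voxel_mm)
  offs <- expand.grid(i = -k:k, j = -k:k, l = -k:k)
  sum(voxel_mm^2 * (offs$i^2 + offs$j^2 + offs$l^2) <= radius_mm^2 + 1e-9)
}
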