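#' Second-level one-sample t-test
#'
#' Voxelwise random-effects t-test of the subject maps' mean against zero
#' (`df = n - 1`, two-sided p). Voxels with zero between-subject variance are
#' handled conservatively: t is set to 0 and p to 1 (never significant), and
#' their count is recorded.
#'
#' @param maps List of per-subject [stat_map()]s on a shared grid/mask.
#' @return A `group_fit` with `t` and `p` [stat_map()]s, `df`, `n_subjects`,
#'   `n_degenerate`.
#' @export
one_sample_t <- function(maps) {
  if (length(maps) < 2) {
    stop_socmap("second-level test needs at least 2 subjects", "validation")
  }
  ref <- maps[[1]]
  for (m in maps[-1]) {
    check_same_geometry(ref$affine, m$affine, dim(ref$values), dim(m$values),
                        "subject maps")
  }
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  vals <- vapply(maps, function(m) m$values[mask], numeric(sum(mask)))
  n <- length(maps)
  mu <- rowMeans(vals)
  s <- sqrt(pmax(rowSums((vals - mu)^2), 0) / (n - 1))
  df <- n - 1
  tval <- rep(0, length(mu))
  ok <- s > 0
  tval[ok] <- mu[ok] / (s[ok] / sqrt(n))
  pval <- rep(1, length(mu))
  pval[ok] <- 2 * pt(-abs(tval[ok]), df = df)
  sp <- dim(ref$values)
  fill <- function(v, kind) {
    arr <- array(NaN, dim = sp)
    arr[mask] <- v
    stat_map(arr, kind, ref$affine, mask = mask, feature = ref$feature,
             level = "second", df = df)
  }
  structure(
    list(
      t = fill(tval, "t"), p = fill(pval, "p"), mean = fill(mu, "beta"),
      df = df, n_subjects = n, n_degenerate = sum(!ok)
    ),
    class = "group_fit"
  )
}

#' Second-level paired t-test
#'
#' One-sample t-test applied to the per-subject difference maps `a - b`
#' (bit-for-bit the same computation).
#'
#' @param maps_a,maps_b Lists of per-subject [stat_map()]s; same subjects,
#'   same order (matched by `feature`-agnostic position; subject identity
#'   checked via names when present).
#' @return A `group_fit`.
#' @export
paired_t <- function(maps_a, maps_b) {
  if (length(maps_a) != length(maps_b)) {
    stop_socmap("paired test needs the same subjects in both sets", "pairing")
  }
  na <- names(maps_a)
  nb <- names(maps_b)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb)) {
    stop_socmap("subject names differ between the two sets", "pairing")
  }
  diffs <- purrr::map2(maps_a, maps_b, function(a, b) {
    check_same_geometry(a$affine, b$affine, dim(a$values), dim(b$values),
                        "paired maps")
    stat_map(a$values - b$values, "beta", a$affine, mask = a$mask & b$mask,
             feature = "paired_difference", level = "first")
  })
  one_sample_t(diffs)
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("<group_fit '%s'> n = %d subjects, df = %d, %d degenerate voxels\n",
              x$t$feature, x$n_subjects, x$df, x$n_degenerate))
  invisible(x)
}

#' @export
glance.group_fit <- function(x, ...) {
  tibble::tibble(
    feature = x$t$feature, n_subjects = x$n_subjects, df = x$df,
    max_abs_t = max(abs(in_mask_values(x$t))), n_degenerate = x$n_degenerate
  )
}

#' Voxelwise FDR (Benjamini-Hochberg) significance
#'
#' Benjamini-Hochberg over all in-mask voxels: with sorted p-values, the
#' threshold `p*` is the largest `p_(k) <= k * q / m`; a voxel is significant
#' iff `p <= p*`. Optionally restricted to positive effects (`t > 0`), as
#' used for cumulative activation maps.
#'
#' @param p_map A p-value [stat_map()].
#' @param q FDR level (e.g. 0.05).
#' @param t_map Optional t [stat_map()] for sign restriction.
#' @param positive_only If `TRUE`, significance additionally requires t > 0.
#' @return List: `significance` (0/1 [stat_map()]), `p_star`, `n_significant`.
#' @export
fdr_significance <- function(p_map, q, t_map = NULL, positive_only = FALSE) {
  mask <- p_map$mask
  if (sum(mask) == 0) stop_socmap("empty mask", "validation")
  p <- p_map$values[mask]
  adj <- p.adjust(p, method = "BH")
  sig <- adj <= q
  p_star <- if (any(sig)) max(p[sig]) else 0
  if (positive_only) {
    if (is.null(t_map)) {
      stop_socmap("positive_only needs a t_map", "validation")
    }
    sig <- sig & (t_map$values[mask] > 0)
  }
  arr <- array(NaN, dim = dim(p_map$values))
  arr[mask] <- as.numeric(sig)
  list(
    significance = stat_map(arr, "significance", p_map$affine, mask = mask,
                            feature = p_map$feature, level = p_map$level),
    p_star = p_star,
    n_significant = sum(sig)
  )
}

#' Cumulative overlap map over social features
#'
#' Voxelwise count of features whose significance maps are 1: how many of
#' the (eight social) features were associated with significant activity at
#' each voxel.
#'
#' @param significance_maps List of aligned 0/1 [stat_map()]s.
#' @return An overlap [stat_map()] with integer values 0..length(maps).
#' @export
overlap_map <- function(significance_maps) {
  if (length(significance_maps) == 0) {
    stop_socmap("no significance maps supplied", "validation")
  }
  ref <- significance_maps[[1]]
  for (m in significance_maps[-1]) {
    check_same_geometry(ref$affine, m$affine, dim(ref$values), dim(m$values),
                        "significance maps")
  }
  mask <- Reduce(`&`, lapply(significance_maps, `[[`, "mask"))
  vals <- Reduce(`+`, lapply(significance_maps, `[[`, "values"))
  stat_map(vals, "overlap", ref$affine, mask = mask,
           feature = "social_overlap", level = "second")
}
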