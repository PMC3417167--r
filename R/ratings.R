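#' Average the two raters' tracks
#'
#' Element-wise mean of the raters' samples for every (clip, feature) track.
#' Errors if the raters' tracks do not align sample-by-sample.
#'
#' @param ratings Long rating tibble (`clip_id`, `feature`, `rater`,
#'   `sample_index`, `value`).
#' @return Tibble with columns `clip_id`, `feature`, `sample_index`, `value`
#'   (provenance `"averaged"`).
#' @export
average_raters <- function(ratings) {
  wide <- ratings |>
    tidyr::pivot_wider(
      id_cols = c("clip_id", "feature", "sample_index"),
      names_from = "rater", values_from = "value"
    )
  rater_cols <- setdiff(names(wide), c("clip_id", "feature", "sample_index"))
  vals <- as.matrix(wide[rater_cols])
  if (anyNA(vals)) {
    stop_socmap("rater tracks do not align (unequal lengths for some track)",
                "alignment")
  }
  out <- wide |>
    dplyr::transmute(
      .data$clip_id, .data$feature, .data$sample_index,
      value = rowMeans(vals)
    ) |>
    dplyr::arrange(.data$clip_id, .data$feature, .data$sample_index)
  attr(out, "provenance") <- "averaged"
  out
}

#' Concatenate per-clip tracks in presentation order
#'
#' Joins each feature's per-clip tracks back to back in the order the clips
#' were shown (the stimulus contained no gaps between clips), yielding one
#' continuous track per feature.
#'
#' @param tracks Averaged tibble (`clip_id`, `feature`, `sample_index`, `value`).
#' @param presentation_order Vector of clip ids in presentation order.
#' @return Tibble (`feature`, `sample_index`, `value`) with a global,
#'   gap-free sample index per feature.
#' @export
concatenate_clips <- function(tracks, presentation_order) {
  feats <- unique(tracks$feature)
  have <- tracks |> dplyr::distinct(.data$clip_id, .data$feature)
  need <- tidyr::expand_grid(clip_id = presentation_order, feature = feats)
  miss <- dplyr::anti_join(need, have, by = c("clip_id", "feature"))
  if (nrow(miss) > 0) {
    stop_socmap(
      sprintf("missing tracks for %d clip/feature combinations (first: %s / %s)",
              nrow(miss), miss$clip_id[1], miss$feature[1]),
      "completeness"
    )
  }
  ordered <- tracks |>
    dplyr::filter(.data$clip_id %in% presentation_order) |>
    dplyr::mutate(.clip_pos = match(.data$clip_id, presentation_order)) |>
    dplyr::arrange(.data$feature, .data$.clip_pos, .data$sample_index)
  out <- ordered |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(sample_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("feature", "sample_index", "value")
  attr(out, "provenance") <- "concatenated"
  out
}

#' Down-sample rating tracks to the acquisition grid
#'
#' Anti-aliasing down-sampling: output volume k is the mean of all raw
#' samples whose time centers fall in `[(k-1) * tr_s, k * tr_s)`. Raw sample
#' i is centred at `(i - 0.5) / rate_hz` seconds. The partial final window is
#' dropped, so each feature yields `floor(duration / tr_s)` volumes.
#'
#' @param tracks Tibble (`feature`, `sample_index`, `value`) of concatenated
#'   tracks (or any per-feature track on a uniform grid).
#' @param rate_hz Sampling rate of the raw tracks.
#' @param tr_s Repetition time of the acquisition.
#' @return Tibble (`feature`, `volume_index`, `value`) with attributes
#'   `tr_s` and provenance `"downsampled"`.
#' @export
downsample_to_tr <- function(tracks, rate_hz, tr_s) {
  if (rate_hz * tr_s <= 1) {
    stop_socmap("rate_hz * tr_s must exceed 1 (every TR window must contain samples)",
                "validation")
  }
  out <- tracks |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(
      .t_center = (.data$sample_index - 0.5) / rate_hz,
      .n_out = floor((dplyr::n() / rate_hz) / tr_s),
      volume_index = floor(.data$.t_center / tr_s) + 1
    ) |>
    dplyr::filter(.data$volume_index <= .data$.n_out) |>
    dplyr::group_by(.data$feature, .data$volume_index) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$feature, .data$volume_index)
  attr(out, "tr_s") <- tr_s
  attr(out, "provenance") <- "downsampled"
  out
}

#' Inter-rater reliability per feature
#'
#' Pearson correlation between the two raters' concatenated tracks, one r
#' per feature; the unweighted mean across features summarizes overall
#' agreement.
#'
#' @param ratings Long rating tibble with exactly two raters.
#' @return Tibble (`feature`, `r`) with attribute `mean_r`.
#' @export
interrater_reliability <- function(ratings) {
  raters <- sort(unique(ratings$rater))
  if (length(raters) != 2) {
    stop_socmap("reliability needs exactly two raters", "validation")
  }
  wide <- ratings |>
    tidyr::pivot_wider(
      id_cols = c("clip_id", "feature", "sample_index"),
      names_from = "rater", values_from = "value"
    )
  a <- wide[[as.character(raters[1])]]
  b <- wide[[as.character(raters[2])]]
  if (anyNA(a) || anyNA(b)) {
    stop_socmap("rater tracks do not align", "alignment")
  }
  out <- wide |>
    dplyr::mutate(.a = a, .b = b) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(r = {
      if (sd(.data$.a) == 0 || sd(.data$.b) == 0) {
        stop_socmap("zero-variance track: correlation undefined", "undefined_correlation")
      }
      cor(.data$.a, .data$.b)
    }, .groups = "drop")
  attr(out, "mean_r") <- mean(out$r)
  out
}

#' Between-feature correlation matrix of the regressors
#'
#' Pairwise Pearson correlations between the mean-rating (or regressor)
#' time courses of each feature.
#'
#' @param timecourses Long tibble (`feature`, index column, `value`) or a
#'   numeric matrix with one column per feature.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
feature_correlation_matrix <- function(timecourses) {
  m <- timecourse_matrix(timecourses)
  if (any(apply(m, 2, sd) == 0)) {
    stop_socmap("zero-variance regressor: correlation undefined", "undefined_correlation")
  }
  cor(m)
}

#' Mean absolute off-diagonal correlation
#'
#' @param corr A correlation matrix.
#' @return Mean |r| over the strictly lower triangle.
#' @export
mean_abs_offdiag <- function(corr) {
  mean(abs(corr[lower.tri(corr)]))
}

# Long (feature, <index>, value) tibble -> time x feature matrix, preserving
# first-appearance feature order. Matrices pass through.
timecourse_matrix <- function(timecourses) {
  if (is.matrix(timecourses)) return(timecourses)
  idx_col <- intersect(c("volume_index", "sample_index"), names(timecourses))[1]
  if (is.na(idx_col)) {
    stop_socmap("timecourses need a volume_index or sample_index column", "validation")
  }
  feats <- unique(timecourses$feature)
  wide <- timecourses |>
    dplyr::arrange(match(.data$feature, feats), .data[[idx_col]]) |>
    tidyr::pivot_wider(
      id_cols = dplyr::all_of(idx_col),
      names_from = "feature", values_from = "value"
    ) |>
    dplyr::arrange(.data[[idx_col]])
  m <- as.matrix(wide[feats])
  if (anyNA(m)) {
    stop_socmap("timecourses have unequal lengths across features", "alignment")
  }
  m
}

# Matrix -> long tibble on the acquisition grid.
timecourse_tibble <- function(m, index_name = "volume_index") {
  tibble::tibble(
    feature = rep(colnames(m), each = nrow(m)),
    !!index_name := rep(seq_len(nrow(m)), times = ncol(m)),
    value = as.vector(m)
  )
}
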