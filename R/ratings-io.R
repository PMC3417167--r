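#' Read / write a long-format rating table
#'
#' Rating tracks are stored as long-format TSV with columns `clip_id`,
#' `feature`, `rater`, `sample_index`, `value`. Values must lie on the 1-5
#' prominence scale; every (clip, feature, rater) track must have contiguous
#' sample indices 1..n with no duplicates.
#'
#' @param path TSV file path.
#' @return A validated tibble of rating samples.
#' @export
read_rating_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_rating_table(tbl)
}

#' @rdname read_rating_table
#' @param ratings A rating tibble.
#' @export
write_rating_table <- function(ratings, path) {
  readr::write_tsv(validate_rating_table(ratings), path, progress = FALSE)
  invisible(path)
}

#' Validate a rating table
#'
#' @param ratings Tibble with columns `clip_id`, `feature`, `rater`,
#'   `sample_index`, `value`.
#' @param scale Allowed value bounds (default `c(1, 5)`).
#' @return The tibble, invisibly validated (returned for piping).
#' @export
validate_rating_table <- function(ratings, scale = c(1, 5)) {
  need <- c("clip_id", "feature", "rater", "sample_index", "value")
  missing_cols <- setdiff(need, names(ratings))
  if (length(missing_cols) > 0) {
    stop_socmap(
      paste0("rating table lacks columns: ", paste(missing_cols, collapse = ", ")),
      "validation"
    )
  }
  if (any(!is.finite(ratings$value))) {
    stop_socmap("rating values must be finite", "validation")
  }
  if (any(ratings$value < scale[1] - 1e-9 | ratings$value > scale[2] + 1e-9)) {
    stop_socmap(
      sprintf("rating values outside the [%g, %g] scale", scale[1], scale[2]),
      "validation"
    )
  }
  key <- paste(ratings$clip_id, ratings$feature, ratings$rater, ratings$sample_index,
               sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop_socmap("duplicated (clip, feature, rater, sample) rows", "duplicate_key")
  }
  gaps <- ratings |>
    dplyr::group_by(.data$clip_id, .data$feature, .data$rater) |>
    dplyr::summarise(
      ok = all(sort(.data$sample_index) == seq_along(.data$sample_index)),
      .groups = "drop"
    )
  if (any(!gaps$ok)) {
    stop_socmap("tracks with missing samples (sample_index not contiguous from 1)",
                "gap")
  }
  ratings
}
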