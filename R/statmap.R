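#' A per-voxel statistical map
#'
#' Holds one 3D image of voxelwise statistics (beta, t, p, binary
#' significance, or overlap counts) with its affine, mask, and degrees of
#' freedom. Values outside the mask are `NaN` by convention.
#'
#' @param values Real (or integer) 3D array.
#' @param kind One of `"beta"`, `"t"`, `"p"`, `"significance"`, `"overlap"`.
#' @param affine 4x4 voxel-to-world transform.
#' @param mask Logical 3D array; defaults to finite voxels of `values`.
#' @param feature Feature or contrast label.
#' @param level `"first"` or `"second"`.
#' @param df Degrees of freedom, where applicable.
#' @return A `stat_map` object.
#' @export
stat_map <- function(values, kind, affine, mask = NULL, feature = NA_character_,
                     level = c("first", "second"), df = NA_real_) {
  kind <- match.arg(kind, c("beta", "t", "p", "significance", "overlap"))
  level <- match.arg(level)
  if (length(dim(values)) != 3L) {
    stop_socmap("values must be a 3D array", "geometry")
  }
  if (is.null(mask)) mask <- array(is.finite(values), dim = dim(values))
  if (!identical(dim(mask), dim(values))) {
    stop_socmap("mask grid does not match values", "geometry")
  }
  v <- values
  v[!mask] <- NaN
  if (kind == "p") {
    inm <- v[mask]
    if (any(inm < -1e-12 | inm > 1 + 1e-12, na.rm = TRUE)) {
      stop_socmap("p values must lie in [0, 1]", "validation")
    }
  }
  structure(
    list(values = v, kind = kind, feature = feature, level = level,
         affine = affine, mask = array(as.logical(mask), dim = dim(values)),
         df = df),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  rng <- range(x$values[x$mask], na.rm = TRUE)
  cat(sprintf(
    "<stat_map %s '%s' level=%s> %s grid, %d in mask, range [%.4g, %.4g], df=%s\n",
    x$kind, x$feature, x$level, paste(dim(x$values), collapse = "x"),
    sum(x$mask), rng[1], rng[2], format(x$df)
  ))
  invisible(x)
}

in_mask_values <- function(map) map$values[map$mask]

#' Write / read a stat map as NIfTI (+ JSON sidecar)
#'
#' The round trip preserves voxel values to stored (double) precision, the
#' affine bit-exactly, and the `NaN`-outside-mask convention.
#'
#' @param map A [stat_map()].
#' @param path Output NIfTI path.
#' @return `write_stat_map()` returns `path` invisibly; `read_stat_map()`
#'   returns a [stat_map()].
#' @export
write_stat_map <- function(map, path) {
  if (is.null(map$affine) || !all(is.finite(map$affine))) {
    stop_socmap("stat map has no valid affine", "validation")
  }
  write_nifti_array(map$values, map$affine, path)
  jsonlite::write_json(
    list(kind = map$kind, feature = map$feature, level = map$level, df = map$df),
    nifti_sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(path) {
  vol <- read_nifti_array(path)
  meta <- list(kind = "beta", feature = NA_character_, level = "first", df = NA_real_)
  sp <- nifti_sidecar_path(path)
  if (file.exists(sp)) {
    got <- jsonlite::read_json(sp, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  stat_map(
    values = vol$data, kind = meta$kind, affine = vol$affine,
    mask = array(!is.nan(vol$data), dim = dim(vol$data)),
    feature = if (is.null(meta$feature)) NA_character_ else meta$feature,
    level = meta$level,
    df = if (is.null(meta$df)) NA_real_ else as.numeric(meta$df)
  )
}
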