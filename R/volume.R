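#' A subject's masked 4D BOLD series
#'
#' Container for one subject's functional run: a 4D array (x, y, z, t) in
#' arbitrary signal units, the voxel-to-world (MNI mm) affine, the repetition
#' time, a boolean brain mask on the same grid, and the number of initial
#' volumes already discarded. All statistics downstream are computed only
#' over mask-true voxels.
#'
#' @param data Real 4D array (x, y, z, t).
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices to mm).
#' @param tr_s Repetition time in seconds.
#' @param mask Logical 3D array matching the spatial grid (default: all TRUE).
#' @param subject_id Subject identifier string.
#' @param n_discarded Number of initial volumes already removed.
#' @return A `volume_series` object.
#' @export
volume_series <- function(data, affine, tr_s, mask = NULL,
                          subject_id = "subject", n_discarded = 0L) {
  if (length(dim(data)) != 4L) {
    stop_socmap("data must be a 4D array (x, y, z, t)", "geometry")
  }
  if (dim(data)[4] < 2L) {
    stop_socmap("series must contain at least 2 volumes", "empty_series")
  }
  if (!is.numeric(tr_s) || tr_s <= 0) {
    stop_socmap("tr_s must be positive", "validation")
  }
  sp <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = sp)
  if (!identical(dim(mask), sp)) {
    stop_socmap("mask grid does not match the spatial grid of data", "geometry")
  }
  structure(
    list(
      data = data, affine = affine, tr_s = tr_s,
      mask = array(as.logical(mask), dim = sp),
      subject_id = subject_id, n_discarded = as.integer(n_discarded)
    ),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_series '%s'> %d x %d x %d voxels, %d volumes (TR %.3f s, %d discarded), %d in mask\n",
    x$subject_id, d[1], d[2], d[3], d[4], x$tr_s, x$n_discarded, sum(x$mask)
  ))
  invisible(x)
}

n_volumes <- function(x) dim(x$data)[4]

# Time x voxel matrix of a volume series (all voxels, column = flat index).
series_matrix <- function(x) {
  d <- dim(x$data)
  t(matrix(x$data, nrow = prod(d[1:3]), ncol = d[4]))
}

nifti_sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

write_nifti_array <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(affine) <- list(dim = c(4L, 4L))
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  list(data = data, affine = affine)
}

#' Read a 4D NIfTI series with its brain mask
#'
#' Reads a 4D NIfTI-1 file and a binary mask on the same grid, removes the
#' first `n_discard` volumes (equilibration scans), and records how many were
#' removed. The repetition time is taken from the JSON sidecar written by
#' [write_volume_series()] when present, otherwise from `tr_s`.
#'
#' @param path Path to the 4D NIfTI file.
#' @param mask_path Path to the mask NIfTI (same grid), or `NULL` for all-TRUE.
#' @param n_discard Number of initial volumes to drop.
#' @param tr_s Fallback repetition time in seconds.
#' @param subject_id Fallback subject identifier.
#' @return A [volume_series()].
#' @export
read_volume_series <- function(path, mask_path = NULL, n_discard = 0L,
                               tr_s = 2.112, subject_id = NULL) {
  vol <- read_nifti_array(path)
  if (length(dim(vol$data)) != 4L) {
    stop_socmap("file does not contain a 4D series", "geometry")
  }
  nt <- dim(vol$data)[4]
  if (nt <= n_discard) {
    stop_socmap(
      sprintf("series has %d volumes; cannot discard %d", nt, n_discard),
      "empty_series"
    )
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_nifti_array(mask_path)
    if (!identical(dim(m$data)[1:3], dim(vol$data)[1:3])) {
      stop_socmap("mask grid does not match the series grid", "geometry")
    }
    check_same_geometry(m$affine, vol$affine, dim(m$data)[1:3], dim(vol$data)[1:3],
                        "mask and series")
    mask <- m$data > 0
  }
  meta <- list()
  sp <- nifti_sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  data <- vol$data[, , , (n_discard + 1L):nt, drop = FALSE]
  volume_series(
    data = data, affine = vol$affine,
    tr_s = if (!is.null(meta$tr_s)) meta$tr_s else tr_s,
    mask = mask,
    subject_id = if (!is.null(subject_id)) subject_id
                 else if (!is.null(meta$subject_id)) meta$subject_id
                 else sub("\\.nii(\\.gz)?$", "", basename(path)),
    n_discarded = n_discard
  )
}

#' Write a volume series to NIfTI (+ JSON sidecar)
#'
#' @param series A [volume_series()].
#' @param path Output NIfTI path.
#' @param mask_path Optional path for the mask NIfTI.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(series, path, mask_path = NULL) {
  write_nifti_array(series$data, series$affine, path)
  jsonlite::write_json(
    list(tr_s = series$tr_s, subject_id = series$subject_id,
         n_discarded = series$n_discarded),
    nifti_sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(mask_path)) {
    write_nifti_array(array(as.numeric(series$mask), dim = dim(series$mask)),
                      series$affine, mask_path)
  }
  invisible(path)
}
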