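# Internal helpers: classed conditions, seeded evaluation, affine geometry.

stop_socmap <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("socmap_error_", class), "socmap_error"), ...)
}

#' Derive a child seed for an indexed sub-stream
#'
#' All stochastic stages draw from one user-supplied seed; independent
#' sub-streams (e.g. per-subject noise) use deterministic child seeds so that
#' results are replayable and subjects are independent.
#'
#' @param seed Integer base seed (or `NULL` for none).
#' @param index Non-negative integer stream index.
#' @return An integer seed below 2^31, or `NULL` if `seed` is `NULL`.
#' @export
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# World-space (mm) coordinates of voxel centers. Voxel indices are 0-based in
# the NIfTI convention; R arrays are 1-based, so array index i maps to voxel
# index i - 1 before going through the affine.
voxel_centers_mm <- function(affine, dim3) {
  ijk <- as.matrix(expand.grid(
    i = seq_len(dim3[1]) - 1L,
    j = seq_len(dim3[2]) - 1L,
    k = seq_len(dim3[3]) - 1L
  ))
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

# Map a single world coordinate to the nearest (1-based) array index.
world_to_index <- function(affine, xyz) {
  ijk <- solve(affine, c(xyz, 1))[1:3]
  as.integer(round(ijk)) + 1L
}

check_same_geometry <- function(affine_a, affine_b, dim_a, dim_b, what = "inputs") {
  if (!isTRUE(all.equal(dim_a, dim_b, check.attributes = FALSE)) ||
      max(abs(affine_a - affine_b)) > 1e-6) {
    stop_socmap(sprintf("%s are not on the same voxel grid", what), "geometry")
  }
  invisible(TRUE)
}

flat_index <- function(dim3) prod(dim3[1:3])
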