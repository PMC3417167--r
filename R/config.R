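#' Run configuration
#'
#' Holds every tunable constant of the pipeline, with defaults matching the
#' study design this package emulates: TR 2.112 s, 5 Hz rating sampling,
#' 128 s high-pass cutoff, FDR q = 0.05, 3 mm beta-summary spheres, 6 mm
#' connectivity spheres, one million permutations with a minimum circular
#' shift of 10 samples, and 100 community-detection restarts. Constants are
#' never hard-coded at call sites; stages read them from the config.
#'
#' @param tr_s Repetition time in seconds.
#' @param rating_rate_hz Rating sampling rate (Hz).
#' @param highpass_cutoff_s High-pass drift cutoff in seconds.
#' @param fdr_q FDR level for voxelwise significance.
#' @param roi_radius_beta_mm Sphere radius (mm) for beta summaries.
#' @param roi_radius_conn_mm Sphere radius (mm) for connectivity time series.
#' @param n_permutations Number of circular-shift permutations.
#' @param min_shift_samples Minimum circular shift (samples).
#' @param n_community_restarts Community-detection restarts.
#' @param rng_seed Base RNG seed (integer or `NULL`).
#' @param hrf_mode `"canonical"` (double-gamma convolution) or `"none"`.
#' @param glm_mode `"per_feature"` (each feature in its own GLM) or
#'   `"combined"` (all 14 at once).
#' @param orthogonalize Whether first-level regressors are mutually
#'   orthogonalized.
#' @param ortho_stage Residualize on the rating time courses (`"pre_hrf"`)
#'   or after HRF convolution (`"post_hrf"`).
#' @return A `run_config` list.
#' @export
run_config <- function(tr_s = 2.112,
                       rating_rate_hz = 5,
                       highpass_cutoff_s = 128,
                       fdr_q = 0.05,
                       roi_radius_beta_mm = 3,
                       roi_radius_conn_mm = 6,
                       n_permutations = 1e6,
                       min_shift_samples = 10,
                       n_community_restarts = 100,
                       rng_seed = NULL,
                       hrf_mode = c("canonical", "none"),
                       glm_mode = c("per_feature", "combined"),
                       orthogonalize = FALSE,
                       ortho_stage = c("pre_hrf", "post_hrf")) {
  cfg <- list(
    tr_s = tr_s,
    rating_rate_hz = rating_rate_hz,
    highpass_cutoff_s = highpass_cutoff_s,
    fdr_q = fdr_q,
    roi_radius_beta_mm = roi_radius_beta_mm,
    roi_radius_conn_mm = roi_radius_conn_mm,
    n_permutations = n_permutations,
    min_shift_samples = min_shift_samples,
    n_community_restarts = n_community_restarts,
    rng_seed = rng_seed,
    hrf_mode = match.arg(hrf_mode),
    glm_mode = match.arg(glm_mode),
    orthogonalize = isTRUE(orthogonalize),
    ortho_stage = match.arg(ortho_stage)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  pos <- c("tr_s", "rating_rate_hz", "highpass_cutoff_s", "fdr_q",
           "roi_radius_beta_mm", "roi_radius_conn_mm")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop_socmap(sprintf("config field '%s' must be a positive number", f), "validation")
    }
  }
  if (cfg$min_shift_samples < 1) {
    stop_socmap("min_shift_samples must be at least 1", "validation")
  }
  if (cfg$n_permutations < 1) {
    stop_socmap("n_permutations must be at least 1", "validation")
  }
  if (cfg$n_community_restarts < 1) {
    stop_socmap("n_community_restarts must be at least 1", "validation")
  }
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(run_config)))
  do.call(run_config, raw[keep])
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
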