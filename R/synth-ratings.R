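#' Generate synthetic two-rater clip rating tracks
#'
#' Emulates continuous prominence ratings of short movie clips: per clip,
#' latent feature tracks are correlated Gaussian processes (squared-
#' exponential kernel, length-scale ~2 s) mapped through a smooth monotone
#' squashing onto the 1-5 scale; each rater's track adds independent smooth
#' noise on the latent scale before squashing. Defaults reproduce the study
#' design: 137 clips of 16.6 +/- 2.7 s sampled at 5 Hz, 14 features, rater
#' noise calibrated for inter-rater r near 0.78, and a correlation target
#' whose realized mean between-feature |r| is near 0.18.
#'
#' @param n_clips Number of clips.
#' @param duration_mean_s,duration_sd_s Clip duration distribution (s).
#' @param duration_range_s Truncation bounds for clip durations.
#' @param features Feature tibble ([default_features()]).
#' @param corr_target Target latent correlation matrix (PSD, unit diagonal).
#' @param rater_noise_sd Rater noise SD on the latent (unit-variance) scale;
#'   the Gaussian-scale inter-rater correlation is `1 / (1 + sd^2)`.
#' @param rate_hz Sampling rate of the rating tracks.
#' @param length_scale_s Gaussian-process length scale in seconds.
#' @param seed RNG seed.
#' @return A `rating_set`: `ratings` (long tibble, two raters), `latent`
#'   (noise-free tracks), `clips` (durations), `presentation_order`.
#' @export
generate_ratings <- function(n_clips = 137,
                             duration_mean_s = 16.6,
                             duration_sd_s = 2.7,
                             duration_range_s = c(10.3, 27.3),
                             features = default_features(),
                             corr_target = default_feature_corr(features),
                             rater_noise_sd = 0.52,
                             rate_hz = 5,
                             length_scale_s = 2,
                             seed = NULL) {
  if (n_clips < 1) stop_socmap("n_clips must be at least 1", "validation")
  check_corr_matrix(corr_target)
  fn <- features$feature
  nf <- length(fn)
  if (nrow(corr_target) != nf) {
    stop_socmap("corr_target dimension does not match the feature count", "validation")
  }
  cr <- chol(corr_target + diag(1e-9, nf))
  with_seed(seed, {
    durations <- rtruncnorm(n_clips, duration_mean_s, duration_sd_s, duration_range_s)
    clip_ids <- sprintf("clip_%03d", seq_len(n_clips))
    per_clip <- lapply(seq_len(n_clips), function(ci) {
      n <- max(2L, as.integer(round(durations[ci] * rate_hz)))
      tt <- (seq_len(n) - 0.5) / rate_hz
      kmat <- exp(-outer(tt, tt, "-")^2 / (2 * length_scale_s^2)) + diag(1e-8, n)
      lk <- chol(kmat)
      draw_gp <- function() crossprod(lk, matrix(rnorm(n * nf), n, nf))
      latent <- draw_gp() %*% cr
      rater_tracks <- lapply(1:2, function(r) {
        g <- latent + rater_noise_sd * (draw_gp() %*% cr)
        squash_rating(g)
      })
      list(
        n = n,
        latent = squash_rating(latent),
        r1 = rater_tracks[[1]],
        r2 = rater_tracks[[2]]
      )
    })
    ratings <- purrr::map2_dfr(clip_ids, per_clip, function(id, cl) {
      tibble::tibble(
        clip_id = id,
        feature = rep(rep(fn, each = cl$n), times = 2),
        rater = rep(c("rater_1", "rater_2"), each = cl$n * nf),
        sample_index = rep(rep(seq_len(cl$n), times = nf), times = 2),
        value = c(as.vector(cl$r1), as.vector(cl$r2))
      )
    })
    latent <- purrr::map2_dfr(clip_ids, per_clip, function(id, cl) {
      tibble::tibble(
        clip_id = id,
        feature = rep(fn, each = cl$n),
        sample_index = rep(seq_len(cl$n), times = nf),
        value = as.vector(cl$latent)
      )
    })
    structure(
      list(
        ratings = ratings,
        latent = latent,
        clips = tibble::tibble(
          clip_id = clip_ids,
          duration_s = vapply(per_clip, function(cl) cl$n / rate_hz, numeric(1)),
          n_samples = vapply(per_clip, `[[`, integer(1), "n")
        ),
        presentation_order = sample(clip_ids),
        features = features,
        rate_hz = rate_hz
      ),
      class = "rating_set"
    )
  })
}

# Smooth monotone map from the latent Gaussian scale onto [1, 5].
squash_rating <- function(g) 3 + 2 * tanh(g / 2)

rtruncnorm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * n, mean, sd)
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
  }
  out[seq_len(n)]
}

#' @export
print.rating_set <- function(x, ...) {
  cat(sprintf(
    "<rating_set> %d clips (%.1f +/- %.1f s), %d features x 2 raters at %g Hz\n",
    nrow(x$clips), mean(x$clips$duration_s), sd(x$clips$duration_s),
    nrow(x$features), x$rate_hz
  ))
  invisible(x)
}

#' Regressors on the acquisition grid from a rating set
#'
#' Convenience chain: average the raters, concatenate clips in presentation
#' order, and down-sample to the TR grid.
#'
#' @param rating_set A [generate_ratings()] result (or compatible list).
#' @param tr_s Repetition time (s).
#' @param n_volumes Optional truncation to the scan length (e.g. the session
#'   stops before the last clips finish).
#' @return Tibble (`feature`, `volume_index`, `value`).
#' @export
ratings_to_regressors <- function(rating_set, tr_s, n_volumes = NULL) {
  down <- rating_set$ratings |>
    average_raters() |>
    concatenate_clips(rating_set$presentation_order) |>
    downsample_to_tr(rate_hz = rating_set$rate_hz, tr_s = tr_s)
  if (!is.null(n_volumes)) {
    have <- max(down$volume_index)
    if (have < n_volumes) {
      stop_socmap(sprintf("ratings cover only %d volumes (< %d)", have, n_volumes),
                  "validation")
    }
    down <- dplyr::filter(down, .data$volume_index <= n_volumes)
  }
  down
}
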