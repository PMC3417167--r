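#' The default stimulus feature set
#'
#' Eight social features (faces, human bodies, biological motion,
#' goal-oriented action, emotion, social interaction, pain, speech) and six
#' non-social filler features (places, objects, rigid motion, people not in
#' social interaction, non-goal-oriented action, non-human sounds), each rated
#' on a 1 (not present) to 5 (present very clearly) prominence scale.
#'
#' @return A tibble with columns `feature` and logical `social`.
#' @export
default_features <- function() {
  tibble::tibble(
    feature = c(
      "faces", "bodies", "biological_motion", "goal_oriented_action",
      "emotion", "social_interaction", "pain", "speech",
      "places", "objects", "rigid_motion", "people_no_interaction",
      "non_goal_action", "nonhuman_sounds"
    ),
    social = rep(c(TRUE, FALSE), c(8L, 6L))
  )
}

#' Names of the social / non-social features
#' @return Character vector of feature names.
#' @export
social_features <- function() default_features()$feature[default_features()$social]

#' @rdname social_features
#' @export
nonsocial_features <- function() default_features()$feature[!default_features()$social]

#' Default between-feature correlation target
#'
#' Target correlation matrix for the latent rating tracks of the synthetic
#' generator. The structure follows what feature-rated movie stimuli look
#' like: most pairs are weakly dependent, a handful of conceptually coupled
#' pairs (faces with social interaction, objects with rigid motion, bodies
#' with biological motion, ...) reach r around 0.5, and social/non-social
#' pairs are essentially independent. The overall mean off-diagonal |r| lands
#' near 0.18 on the realized rating scale.
#'
#' @param features Tibble from [default_features()].
#' @return A 14 x 14 positive semi-definite correlation matrix.
#' @export
default_feature_corr <- function(features = default_features()) {
  fn <- features$feature
  n <- length(fn)
  soc <- features$social
  r <- matrix(0.09, n, n, dimnames = list(fn, fn))
  r[soc, soc] <- 0.23
  r[!soc, !soc] <- 0.23
  set_pair <- function(m, a, b, v) {
    m[a, b] <- v
    m[b, a] <- v
    m
  }
  r <- set_pair(r, "faces", "social_interaction", 0.50)
  r <- set_pair(r, "speech", "social_interaction", 0.40)
  r <- set_pair(r, "faces", "speech", 0.35)
  r <- set_pair(r, "emotion", "social_interaction", 0.40)
  r <- set_pair(r, "emotion", "pain", 0.35)
  r <- set_pair(r, "bodies", "biological_motion", 0.45)
  r <- set_pair(r, "biological_motion", "goal_oriented_action", 0.35)
  r <- set_pair(r, "bodies", "goal_oriented_action", 0.30)
  r <- set_pair(r, "objects", "rigid_motion", 0.50)
  r <- set_pair(r, "places", "objects", 0.30)
  r <- set_pair(r, "people_no_interaction", "non_goal_action", 0.35)
  r <- set_pair(r, "rigid_motion", "non_goal_action", 0.30)
  r <- set_pair(r, "bodies", "people_no_interaction", 0.25)
  diag(r) <- 1
  r
}

check_corr_matrix <- function(m, what = "corr_target") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_socmap(sprintf("%s must be a square matrix", what), "validation")
  }
  if (max(abs(m - t(m))) > 1e-10 || max(abs(diag(m) - 1)) > 1e-10) {
    stop_socmap(sprintf("%s must be symmetric with unit diagonal", what), "validation")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_socmap(sprintf("%s is not positive semi-definite", what), "validation")
  }
  invisible(TRUE)
}
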