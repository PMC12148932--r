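#' The four fixed landmark environments
#'
#' Landmark configurations used by the internal-map task (and by the fixed
#' landmark test configurations). Pairwise angular distances are unique
#' enough across the four maps to allow inference of environment identity
#' from the sequence of landmark encounters alone.
#'
#' @param id one of `"e1"`..`"e4"`.
#' @return an `environment_map` object: list with `landmarks` (angles, rad)
#'   and `env_id`.
#' @export
fixed_environment <- function(id = c("e1", "e2", "e3", "e4")) {
  id <- match.arg(id)
  lms <- switch(id,
    e1 = c(0, 2 * pi / 3),
    e2 = c(1.9562, 3.7471),
    e3 = c(0.2641, 1.2920, 3.7243),
    e4 = c(3.0511, 3.8347, 5.1625, 5.7165))
  new_environment(lms, env_id = id)
}

new_environment <- function(landmarks, env_id = NULL) {
  structure(list(landmarks = wrap_angle(landmarks), env_id = env_id),
            class = "environment_map")
}

#' Construct a landmark environment
#'
#' Builds an `environment_map` from explicit landmark angles, enforcing the
#' task invariants: 2 to 4 landmarks with pairwise circular distance at
#' least `min_sep`.
#'
#' @param landmarks angles (rad).
#' @param env_id optional label.
#' @param min_sep minimum pairwise separation to enforce (rad).
#' @return an `environment_map`.
#' @export
landmark_environment <- function(landmarks, env_id = NULL,
                                 min_sep = pi / 9) {
  stopifnot(length(landmarks) >= 2, length(landmarks) <= 4)
  if (length(landmarks) > 1) {
    d <- as.numeric(dist(wrap_angle(landmarks)))
    d <- pmin(d, 2 * pi - d)
    if (min(d) < min_sep)
      stop("landmarks closer than the minimum separation")
  }
  new_environment(landmarks, env_id)
}

#' Sample a random landmark environment
#'
#' The first landmark is uniform on the circle; each subsequent landmark is
#' drawn uniformly by rejection until its minimum circular distance from all
#' previously placed landmarks is at least `cfg$delta_sep` (default pi/9 rad).
#'
#' @param K number of landmarks, 2 to 4.
#' @param cfg a [sim_config()].
#' @return an `environment_map`.
#' @export
sample_environment <- function(K, cfg = sim_config()) {
  stopifnot(K %in% 2:4)
  lms <- runif(1, 0, 2 * pi)
  while (length(lms) < K) {
    cand <- runif(1, 0, 2 * pi)
    if (min(circ_dist(cand, lms)) >= cfg$delta_sep) lms <- c(lms, cand)
  }
  new_environment(lms)
}

#' @export
print.environment_map <- function(x, ...) {
  cat(sprintf("environment%s: %d landmarks at {%s} rad\n",
              if (is.null(x$env_id)) "" else paste0(" ", x$env_id),
              length(x$landmarks),
              paste(sprintf("%.3f", x$landmarks), collapse = ", ")))
  invisible(x)
}
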