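#' Sample a random-acceleration trajectory
#'
#' The agent starts at rest (`v_0 = 0`) at a uniformly random angle. At every
#' step an acceleration is drawn from a zero-mean Gaussian with s.d.
#' `cfg$sigma_a`, truncated at `|a| > cfg$a_max` (clipped to the bound by
#' default, or redrawn when `cfg$truncation == "resample"`). Acceleration is
#' integrated to velocity, which is clipped at `|v| > cfg$v_max`, and velocity
#' is integrated to angular position via `y_t = y_{t-1} + v_t * dt / radius`.
#' Positive velocity is counter-clockwise travel.
#'
#' @param cfg a [sim_config()].
#' @param y0 optional initial angle (rad); uniform if `NULL`.
#' @return a `trajectory`: list with per-step `a` (m/s^2), `v` (m/s),
#'   `y` (rad, wrapped) of length `cfg$n_steps`, and scalar `y0`.
#' @export
sample_trajectory <- function(cfg = sim_config(), y0 = NULL) {
  b <- trajectory_batch(cfg, 1L, y0 = y0)
  new_trajectory(b$a[, 1], b$v[, 1], b$y[, 1], b$y0[1])
}

# vectorized core: a batch of independent random trajectories, columns are
# trials; sample_trajectory() is the B = 1 case
trajectory_batch <- function(cfg, B, y0 = NULL) {
  T <- cfg$n_steps
  if (is.null(y0)) y0 <- runif(B, 0, 2 * pi)
  a <- matrix(rnorm(T * B, 0, cfg$sigma_a), T, B)
  if (cfg$truncation == "clip") {
    a <- pmin(pmax(a, -cfg$a_max), cfg$a_max)
  } else {
    bad <- abs(a) > cfg$a_max
    while (any(bad)) {
      a[bad] <- rnorm(sum(bad), 0, cfg$sigma_a)
      bad <- abs(a) > cfg$a_max
    }
  }
  v <- matrix(0, T, B)
  vc <- numeric(B)
  for (t in seq_len(T)) {
    vc <- pmin(pmax(vc + a[t, ] * cfg$dt, -cfg$v_max), cfg$v_max)
    v[t, ] <- vc
  }
  y <- wrap_angle(rep(y0, each = T) +
                    apply(v, 2, cumsum) * cfg$dt / cfg$radius)
  dim(y) <- c(T, B)
  list(a = a, v = v, y = y, y0 = y0)
}

#' Constant-speed trajectory
#'
#' Used by the fixed-velocity test configurations: speed is constant at
#' `speed` (default half the speed cap) with a random initial angle and a
#' random direction of travel.
#'
#' @param cfg a [sim_config()].
#' @param speed absolute speed (m/s).
#' @param y0 optional initial angle (rad).
#' @param direction +1 (CCW) or -1 (CW); random if `NULL`.
#' @return a `trajectory`.
#' @export
constant_trajectory <- function(cfg = sim_config(), speed = cfg$v_max / 2,
                                y0 = NULL, direction = NULL) {
  T <- cfg$n_steps
  if (is.null(y0)) y0 <- runif(1, 0, 2 * pi)
  if (is.null(direction)) direction <- sample(c(-1, 1), 1)
  v <- rep(direction * speed, T)
  y <- wrap_angle(y0 + cumsum(v) * cfg$dt / cfg$radius)
  new_trajectory(a = c(v[1] / cfg$dt, rep(0, T - 1)), v = v, y = y, y0 = y0)
}

new_trajectory <- function(a, v, y, y0) {
  structure(list(a = a, v = v, y = y, y0 = y0), class = "trajectory")
}

#' Detect landmark encounters along a trajectory
#'
#' An encounter is emitted at the first step at which the agent is within
#' `cfg$d_enc` (inclusive) of a landmark *different from the previously
#' encountered one*. Hovering around, or repeatedly approaching, the same
#' landmark triggers nothing after the first approach; at trial start no
#' landmark counts as "previous", so the first proximity to any landmark is
#' an encounter. Because landmarks are at least `delta_sep > 2 * d_enc`
#' apart, at most one landmark is in range at any step.
#'
#' @param traj a `trajectory`.
#' @param env an `environment_map`.
#' @param cfg a [sim_config()].
#' @return an `encounter_log`: data.frame with columns `t` (step index) and
#'   `landmark` (index into `env$landmarks`).
#' @export
detect_encounters <- function(traj, env, cfg = sim_config()) {
  ev <- encounter_core(traj$y, env$landmarks, cfg$d_enc)
  structure(data.frame(t = ev$t, landmark = ev$landmark),
            class = c("encounter_log", "data.frame"))
}

# shared detection logic (also used by the training fast path)
encounter_core <- function(y, lms, d_enc) {
  D <- vapply(lms, function(l) circ_dist(y, l), numeric(length(y)))
  D <- matrix(D, ncol = length(lms))
  near_lm <- max.col(-D, ties.method = "first")
  in_range <- D[cbind(seq_along(near_lm), near_lm)] <= d_enc
  events_t <- integer(0)
  events_lm <- integer(0)
  last <- 0L
  for (t in which(in_range)) {
    if (near_lm[t] != last) {
      events_t <- c(events_t, t)
      events_lm <- c(events_lm, near_lm[t])
      last <- near_lm[t]
    }
  }
  list(t = events_t, landmark = events_lm)
}

#' Corrupt the velocity signal
#'
#' Returns the per-step displacement report available to the agents: the true
#' displacement `v_t * dt` (m) plus zero-mean Gaussian noise of s.d.
#' `cfg$sigma_v` (m per step, default `v_max * dt / 10`).
#'
#' @param traj a `trajectory`.
#' @param cfg a [sim_config()].
#' @return numeric vector of noisy displacements (m), length `cfg$n_steps`.
#' @export
corrupt_velocity <- function(traj, cfg = sim_config()) {
  traj$v * cfg$dt + rnorm(length(traj$v), 0, cfg$sigma_v)
}

#' Corrupt the landmark map
#'
#' At each landmark encounter the map made available to the agents is
#' coherently rotated by a fresh draw from `N(0, sigma_l^2)`; relative
#' landmark positions are unchanged. One independent rotation is drawn per
#' requested encounter.
#'
#' @param env an `environment_map`.
#' @param cfg a [sim_config()]; must use the external-map scheme (there is
#'   no map to corrupt in the internal-map scheme).
#' @param n number of encounters (rows) to draw maps for.
#' @return an `n x K` matrix of rotated landmark angles (rad), one row per
#'   encounter.
#' @export
corrupt_map <- function(env, cfg = sim_config(), n = 1) {
  if (cfg$scheme != "external_map")
    stop("corrupt_map: no map exists under the internal_map scheme")
  rot <- rnorm(n, 0, cfg$sigma_l)
  t(vapply(rot, function(r) wrap_angle(env$landmarks + r),
           numeric(length(env$landmarks))))
}
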