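#' Particle filter configuration
#'
#' @param N_p particle count.
#' @param resample_frac effective-sample-size threshold fraction: particles
#'   are resampled (low-variance/systematic scheme) whenever
#'   `N_eff = 1/sum(w^2) < N_p * resample_frac`.
#' @param enhanced use the enhanced variant, which also prunes particles
#'   that pass within the observation threshold of a landmark (other than
#'   their own last-encountered one) without an encounter being signalled.
#' @param grid_bins resolution of the grid-Bayes oracle.
#' @return a `filter_config`.
#' @export
filter_config <- function(N_p = 1000L, resample_frac = 1 / 5,
                          enhanced = FALSE, grid_bins = 360L) {
  stopifnot(N_p >= 1, resample_frac > 0, resample_frac < 1, grid_bins >= 36)
  structure(list(N_p = as.integer(N_p), resample_frac = resample_frac,
                 enhanced = enhanced, grid_bins = as.integer(grid_bins)),
            class = "filter_config")
}

#' Path integration with landmark correction
#'
#' The simplest agent: starts with a location estimate at `y = 0` (despite
#' the true start being random and unknown), integrates the noisy
#' displacement signal, and at each landmark encounter resets the estimate
#' to the coordinates of the landmark nearest (circular distance) to the
#' current estimate. Ties are broken toward the lowest landmark index.
#'
#' @param noisy_disp noisy displacements (m per step).
#' @param encounters an `encounter_log`.
#' @param env an `environment_map` (the agent corrects against the true map).
#' @param cfg a [sim_config()].
#' @return an `estimate_trace`: data.frame `t, y_hat, circ_var, agent`
#'   (`circ_var` is `NA` for this single-estimate agent).
#' @export
path_integrate_correct <- function(noisy_disp, encounters, env,
                                   cfg = sim_config()) {
  T <- length(noisy_disp)
  step_rad <- noisy_disp / cfg$radius
  enc_at <- integer(T)
  enc_at[encounters$t] <- encounters$landmark
  y_hat <- numeric(T)
  est <- 0
  for (t in seq_len(T)) {
    est <- wrap_angle(est + step_rad[t])
    if (enc_at[t] > 0) {
      d <- circ_dist(est, env$landmarks)
      est <- env$landmarks[which.min(d)]  # which.min takes the lowest index on ties
    }
    y_hat[t] <- est
  }
  new_estimate_trace(y_hat, rep(NA_real_, T), "pi_correct")
}

new_estimate_trace <- function(y_hat, circ_var, agent) {
  structure(data.frame(t = seq_along(y_hat), y_hat = y_hat,
                       circ_var = circ_var, agent = agent),
            class = c("estimate_trace", "data.frame"))
}

#' Low-variance (systematic) resampling
#'
#' Draws `length(w)` particle indices using a single uniform offset, the
#' standard low-variance scheme: the `k`-th index is the particle whose
#' cumulative weight interval contains `(u + k - 1) / N`.
#'
#' @param w normalized weights.
#' @param u optional uniform offset in `[0, 1)`; drawn if `NULL`.
#' @return integer vector of resampled particle indices.
#' @export
systematic_resample <- function(w, u = NULL) {
  N <- length(w)
  if (is.null(u)) u <- runif(1)
  pts <- (u + seq_len(N) - 1) / N
  findInterval(pts, cumsum(w) - 1e-15) + 1L
}

lm_likelihood <- function(angles, noisy_map, cfg) {
  if (cfg$sigma_l > 0) {
    rowSums(vapply(noisy_map, function(l) vm_bump(angles - l, cfg$sigma_l),
                   numeric(length(angles))))
  } else {
    # sigma_l -> 0 limit: evidence that a landmark is observable from here
    D <- vapply(noisy_map, function(l) circ_dist(angles, l),
                numeric(length(angles)))
    as.numeric(apply(matrix(D, ncol = length(noisy_map)), 1, min) <= cfg$d_enc)
  }
}

#' Run a particle filter on one trial
#'
#' Sequential Monte Carlo over location on the circle. `N_p` particles start
#' uniform (or at `init`) with equal weights. Each step every particle moves
#' by the reported displacement plus fresh `N(0, sigma_v^2)` noise. At a
#' landmark encounter the weights are multiplied by the landmark likelihood
#' `sum_i vm_bump(y_particle - l~_i, sigma_l)` over the noise-rotated map
#' for that encounter, and renormalized to sum 1. Whenever
#' `N_eff = 1/sum(w^2)` drops below `N_p * resample_frac` the cloud is
#' resampled systematically and weights equalized.
#'
#' The enhanced variant additionally uses the *absence* of encounters after
#' the first one: each particle tracks which landmark it was nearest to at
#' its last encounter, and a particle that comes within `cfg$d_enc` of a
#' different landmark at a step with no encounter signal is deleted (weight
#' set to 0). If every particle is deleted the cloud is re-drawn uniformly
#' with equal weights.
#'
#' @param noisy_disp noisy displacements (m per step).
#' @param encounters an `encounter_log`.
#' @param noisy_maps per-encounter rotated maps (rows), or `NULL` to use the
#'   true map at every encounter.
#' @param env an `environment_map`.
#' @param cfg a [sim_config()].
#' @param fcfg a [filter_config()].
#' @param init optional fixed initial angle for all particles (for
#'   known-start control experiments); uniform start if `NULL`.
#' @param keep_particles record the full particle history (locations,
#'   weights per step).
#' @return list with `est` (an `estimate_trace`) and, if requested,
#'   `history` (list of per-step `list(y, w)`).
#' @export
pf_run <- function(noisy_disp, encounters, noisy_maps, env,
                   cfg = sim_config(), fcfg = filter_config(),
                   init = NULL, keep_particles = FALSE) {
  T <- length(noisy_disp)
  N <- fcfg$N_p
  step_rad <- noisy_disp / cfg$radius
  sig_step <- cfg$sigma_v / cfg$radius
  enc_idx <- integer(T)
  enc_idx[encounters$t] <- seq_len(nrow(encounters))
  if (is.null(noisy_maps) && nrow(encounters) > 0)
    noisy_maps <- matrix(env$landmarks, nrow(encounters),
                         length(env$landmarks), byrow = TRUE)
  y_p <- if (is.null(init)) runif(N, 0, 2 * pi) else rep(init, N)
  w <- rep(1 / N, N)
  last_lm <- integer(N)            # 0 = no encounter yet, per particle
  seen_first <- FALSE
  y_hat <- numeric(T); cv <- numeric(T)
  hist <- if (keep_particles) vector("list", T) else NULL
  Dfun <- function(p) vapply(env$landmarks, function(l) circ_dist(p, l),
                             numeric(N))
  for (t in seq_len(T)) {
    y_p <- wrap_angle(y_p + step_rad[t] + rnorm(N, 0, sig_step))
    if (enc_idx[t] > 0) {
      lik <- lm_likelihood(y_p, noisy_maps[enc_idx[t], ], cfg)
      w <- w * lik
      if (sum(w) <= 0) {           # degenerate: no particle explains the observation
        y_p <- runif(N, 0, 2 * pi)
        w <- rep(1 / N, N)
        last_lm <- integer(N)
      } else {
        w <- w / sum(w)
        D <- Dfun(y_p)
        last_lm <- max.col(-D, ties.method = "first")
        seen_first <- TRUE
      }
    } else if (fcfg$enhanced && seen_first) {
      D <- Dfun(y_p)
      in_zone <- D <= cfg$d_enc
      in_zone[cbind(which(last_lm > 0), last_lm[last_lm > 0])] <- FALSE
      prune <- rowSums(in_zone) > 0
      if (any(prune)) {
        w[prune] <- 0
        if (sum(w) <= 0) {
          y_p <- runif(N, 0, 2 * pi)
          w <- rep(1 / N, N)
          last_lm <- integer(N)
        } else w <- w / sum(w)
      }
    }
    if (1 / sum(w^2) < N * fcfg$resample_frac) {
      idx <- systematic_resample(w)
      y_p <- y_p[idx]
      last_lm <- last_lm[idx]
      w <- rep(1 / N, N)
    }
    ce <- circular_estimate(y_p, w)
    y_hat[t] <- if (ce$defined) ce$y_hat else NA_real_
    cv[t] <- ce$circ_var
    if (keep_particles) hist[[t]] <- list(y = y_p, w = w)
  }
  agent <- if (fcfg$enhanced) "pf_enhanced" else "pf_basic"
  out <- list(est = new_estimate_trace(y_hat, cv, agent))
  if (keep_particles) out$history <- hist
  out
}

#' Exact grid-Bayes oracle
#'
#' Exact sequential Bayesian inference on a discretized circle, used as the
#' independent reference the particle filters approximate. The posterior
#' over `grid_bins` equally spaced angles is propagated each step by
#' circular convolution with a wrapped Gaussian centred on the reported
#' displacement with s.d. `sigma_v` (computed via FFT), multiplied by the
#' same landmark likelihood kernel as [pf_run()] at encounters, and
#' renormalized every step.
#'
#' @inheritParams pf_run
#' @param grid_bins number of grid angles.
#' @return list with `est` (an `estimate_trace`, agent `"grid_oracle"`),
#'   `posterior` (`T x grid_bins` matrix) and `theta` (grid angles).
#' @export
grid_bayes_oracle <- function(noisy_disp, encounters, noisy_maps, env,
                              cfg = sim_config(), grid_bins = 360L) {
  T <- length(noisy_disp)
  n <- as.integer(grid_bins)
  theta <- (seq_len(n) - 1) * 2 * pi / n
  step_rad <- noisy_disp / cfg$radius
  sig <- cfg$sigma_v / cfg$radius
  enc_idx <- integer(T)
  enc_idx[encounters$t] <- seq_len(nrow(encounters))
  if (is.null(noisy_maps) && nrow(encounters) > 0)
    noisy_maps <- matrix(env$landmarks, nrow(encounters),
                         length(env$landmarks), byrow = TRUE)
  p <- rep(1 / n, n)
  post <- matrix(0, T, n)
  y_hat <- numeric(T); cv <- numeric(T)
  bin <- 2 * pi / n
  # signed FFT frequencies for spectral (exact, sub-bin) rotation
  j <- 0:(n - 1)
  kfreq <- ifelse(j <= n %/% 2, j, j - n)
  wrapped_kernel <- function(mu) {
    d <- circ_diff(theta, mu)
    k <- stats::dnorm(d, 0, sig) + stats::dnorm(d - 2 * pi, 0, sig) +
      stats::dnorm(d + 2 * pi, 0, sig)
    k / sum(k)
  }
  for (t in seq_len(T)) {
    if (sig >= bin / 4) {
      k <- wrapped_kernel(step_rad[t])
      p <- Re(fft(fft(p) * fft(k), inverse = TRUE)) / n
    } else if (abs(step_rad[t]) > 0) {
      # negligible blur relative to the grid: pure spectral rotation
      p <- Re(fft(fft(p) * exp(-1i * kfreq * step_rad[t]),
                  inverse = TRUE)) / n
    }
    p[p < 0] <- 0
    if (enc_idx[t] > 0) {
      p <- p * lm_likelihood(theta, noisy_maps[enc_idx[t], ], cfg)
    }
    s <- sum(p)
    p <- if (s > 0) p / s else rep(1 / n, n)
    post[t, ] <- p
    ce <- circular_estimate(theta, p)
    y_hat[t] <- if (ce$defined) ce$y_hat else NA_real_
    cv[t] <- ce$circ_var
  }
  list(est = new_estimate_trace(y_hat, cv, "grid_oracle"),
       posterior = post, theta = theta)
}

#' Mean absolute circular localization error
#'
#' Averages `circ_dist(y_hat, y)` over the steps of a window: the whole
#' trial, the steps strictly after the first encounter (`"post_lm1"`), or
#' after the second (`"post_lm2"`). Steps with undefined (flagged `NA`)
#' estimates are excluded; their count is reported in the `n_undefined`
#' attribute.
#'
#' @param est an `estimate_trace`.
#' @param traj a `trajectory` with the true positions.
#' @param window `"all"`, `"post_lm1"` or `"post_lm2"`, or a logical/integer
#'   step selector.
#' @param encounters required for the named post-encounter windows.
#' @return mean absolute circular error (rad); `NA` if the window is empty.
#' @export
localization_error <- function(est, traj, window = "all", encounters = NULL) {
  T <- length(traj$y)
  stopifnot(nrow(est) == T)
  sel <- if (is.character(window)) {
    switch(window,
      all = rep(TRUE, T),
      post_lm1 = {
        stopifnot(!is.null(encounters), nrow(encounters) >= 1)
        seq_len(T) > encounters$t[1]
      },
      post_lm2 = {
        stopifnot(!is.null(encounters), nrow(encounters) >= 2)
        seq_len(T) > encounters$t[2]
      },
      stop("unknown window: ", window))
  } else if (is.logical(window)) window else seq_len(T) %in% window
  yh <- est$y_hat[sel]
  yt <- traj$y[sel]
  ok <- !is.na(yh)
  out <- if (any(ok)) mean(circ_dist(yh[ok], yt[ok])) else NA_real_
  attr(out, "n_undefined") <- sum(!ok)
  out
}
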