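#' Configuration of a synthetic population recording
#'
#' Defines a synthetic session emulating the statistical structure of a
#' retrosplenial population recorded during the two-landmark foraging task:
#' 50-90 simultaneous neurons driven by a shared low-dimensional latent
#' process, conjunctive position tuning in a 500 mm circular arena, and
#' phase-dependent (hypothesis-coding) rate offsets, with Poisson spiking.
#'
#' `phase_gain` scales the hypothesis signal: at 0 the phases LM0/LM1a/
#' LM1b/LM2 leave no trace in the rates (decoding falls to chance); at 1
#' each neuron carries its full phase offset. `pos_gain` scales spatial
#' tuning the same way.
#'
#' @param n_neurons neuron count; drawn uniformly from 50-90 when `NULL`.
#' @param sample_rate behavioral/neural sampling rate (Hz).
#' @param n_trials trials per session.
#' @param trial_duration seconds per trial.
#' @param latent_dim dimensionality of the shared smooth latent drive.
#' @param latent_tau latent autocorrelation time constant (s).
#' @param phase_gain hypothesis-coding strength in `[0, 1]`.
#' @param pos_gain spatial-coding strength.
#' @param base_rate mean firing rate per neuron (Hz).
#' @param arena_radius arena radius (mm; 500 mm diameter by default).
#' @param landmark_angles angular positions of landmarks 'a' and 'b' (rad).
#' @return a `session_config`.
#' @export
session_config <- function(n_neurons = NULL, sample_rate = 100,
                           n_trials = 24L, trial_duration = 10,
                           latent_dim = 6L, latent_tau = 1,
                           phase_gain = 0.5, pos_gain = 0.5,
                           base_rate = 5, arena_radius = 250,
                           landmark_angles = c(0, 2 * pi / 3)) {
  stopifnot(is.null(n_neurons) || (n_neurons >= 2),
            sample_rate > 0, n_trials >= 1, trial_duration > 0,
            latent_dim >= 1, latent_tau > 0, phase_gain >= 0, pos_gain >= 0,
            base_rate > 0, arena_radius > 0, length(landmark_angles) == 2)
  structure(list(n_neurons = n_neurons, sample_rate = sample_rate,
                 n_trials = as.integer(n_trials),
                 trial_duration = trial_duration,
                 latent_dim = as.integer(latent_dim), latent_tau = latent_tau,
                 phase_gain = phase_gain, pos_gain = pos_gain,
                 base_rate = base_rate, arena_radius = arena_radius,
                 landmark_angles = wrap_angle(landmark_angles)),
            class = "session_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Generate a synthetic spiking session
#'
#' Per trial: a smooth 2D random walk in the arena disc; two scripted
#' landmark-encounter times defining the phase sequence LM0 -> LM1a/b ->
#' LM2 (the LM1 sub-label records which landmark the *second* encounter
#' will be, drawn with equal probability); a `latent_dim`-dimensional AR(1)
#' latent state mixed through a fixed random loading matrix; per-neuron
#' position tuning (von Mises in arena angle, Gaussian in radius) scaled by
#' `pos_gain`; per-neuron phase offsets scaled by `phase_gain`. The summed
#' drive passes through a softplus, is calibrated so each neuron's mean
#' rate equals `base_rate`, and spikes are drawn as inhomogeneous Poisson
#' counts per sample.
#'
#' @param cfg a [session_config()].
#' @return a `spike_session`: list with `counts` (`N_samples x n_neurons`),
#'   `spikes` (per-neuron spike times, s), `rates` (ground-truth Hz),
#'   `t`, `x`, `y` (mm), `angle`, `radius`, `phase`
#'   (`LM0/LM1a/LM1b/LM2`), `last_lm_angle` (rad; `NA` in LM0), `trial`,
#'   `trial_info` (data.frame: trial, lm1_type, t_enc1, t_enc2, first/second
#'   landmark angles), and `cfg`.
#' @export
synth_session <- function(cfg = session_config()) {
  n_neu <- if (is.null(cfg$n_neurons)) sample(50:90, 1) else cfg$n_neurons
  fs <- cfg$sample_rate
  dt <- 1 / fs
  n_per <- round(cfg$trial_duration * fs)
  n_tr <- cfg$n_trials
  N <- n_per * n_tr
  rho <- exp(-dt / cfg$latent_tau)
  sig_innov <- sqrt(1 - rho^2)

  # fixed session-level neuron properties
  load <- matrix(rnorm(n_neu * cfg$latent_dim), n_neu) / sqrt(cfg$latent_dim)
  pref_ang <- runif(n_neu, 0, 2 * pi)
  ang_width <- runif(n_neu, pi / 4, pi)
  pref_rad <- runif(n_neu, 0, cfg$arena_radius)
  rad_width <- runif(n_neu, cfg$arena_radius / 4, cfg$arena_radius)
  # phase offsets at s.d. 1.5 x the shared-latent scale: phase_gain = 1
  # means clearly decodable hypothesis coding, the generator's defined
  # full-strength endpoint
  phase_off <- matrix(rnorm(n_neu * 4, 0, 1.5), n_neu,
                      dimnames = list(NULL, c("LM0", "LM1a", "LM1b", "LM2")))

  x <- y <- numeric(N)
  phase <- character(N)
  last_lm <- rep(NA_real_, N)
  trial <- rep(seq_len(n_tr), each = n_per)
  tvec <- (seq_len(N) - 1) * dt
  Z <- matrix(0, N, cfg$latent_dim)
  info <- data.frame(trial = seq_len(n_tr), lm1_type = NA_character_,
                     t_enc1 = NA_real_, t_enc2 = NA_real_,
                     first_lm_angle = NA_real_, second_lm_angle = NA_real_)
  for (tr in seq_len(n_tr)) {
    rows <- (tr - 1) * n_per + seq_len(n_per)
    # smooth 2D walk: AR(1) velocity, reflecting at the arena wall
    vx <- vy <- 0
    px <- runif(1, -0.3, 0.3) * cfg$arena_radius
    py <- runif(1, -0.3, 0.3) * cfg$arena_radius
    sp <- 150 * dt  # ~150 mm/s typical speed
    for (i in seq_len(n_per)) {
      vx <- 0.95 * vx + rnorm(1, 0, sp * 0.3)
      vy <- 0.95 * vy + rnorm(1, 0, sp * 0.3)
      px <- px + vx; py <- py + vy
      rr <- sqrt(px^2 + py^2)
      if (rr > cfg$arena_radius) {
        px <- px * cfg$arena_radius / rr
        py <- py * cfg$arena_radius / rr
        vx <- -vx; vy <- -vy
      }
      x[rows[i]] <- px; y[rows[i]] <- py
    }
    # scripted encounters and phase sequence
    t1 <- runif(1, 0.15, 0.35) * cfg$trial_duration
    t2 <- t1 + runif(1, 0.2, 0.4) * cfg$trial_duration
    typ <- sample(c("a", "b"), 1)
    second <- cfg$landmark_angles[match(typ, c("a", "b"))]
    first <- cfg$landmark_angles[match(typ, c("b", "a"))]
    tt <- tvec[rows] - tvec[rows[1]]
    ph <- ifelse(tt < t1, "LM0", ifelse(tt < t2,
                                        paste0("LM1", typ), "LM2"))
    phase[rows] <- ph
    last_lm[rows] <- ifelse(tt < t1, NA_real_, ifelse(tt < t2, first, second))
    info$lm1_type[tr] <- typ
    info$t_enc1[tr] <- t1; info$t_enc2[tr] <- t2
    info$first_lm_angle[tr] <- first; info$second_lm_angle[tr] <- second
    # latent walk restarts each trial (stationary draw)
    z <- rnorm(cfg$latent_dim)
    for (i in seq_len(n_per)) {
      z <- rho * z + sig_innov * rnorm(cfg$latent_dim)
      Z[rows[i], ] <- z
    }
  }
  ang <- wrap_angle(atan2(y, x))
  rad <- sqrt(x^2 + y^2)
  drive <- Z %*% t(load)
  if (cfg$pos_gain > 0) {
    pos_tune <- vm_bump(outer(ang, pref_ang, "-"),
                        matrix(ang_width, N, n_neu, byrow = TRUE)) *
      exp(-0.5 * (outer(rad, pref_rad, "-") /
                    matrix(rad_width, N, n_neu, byrow = TRUE))^2)
    drive <- drive + cfg$pos_gain * 2 * (pos_tune - 0.5)
  }
  if (cfg$phase_gain > 0) {
    drive <- drive + cfg$phase_gain *
      t(phase_off[, phase, drop = FALSE])
  }
  s <- softplus(drive)
  rates <- sweep(s, 2, colMeans(s), "/") * cfg$base_rate
  counts <- matrix(rpois(length(rates), rates * dt), N, n_neu)
  spikes <- lapply(seq_len(n_neu), function(j) {
    idx <- rep.int(seq_len(N), counts[, j])
    sort(tvec[idx] + runif(length(idx), 0, dt))
  })
  structure(list(counts = counts, spikes = spikes, rates = rates,
                 t = tvec, x = x, y = y, angle = ang, radius = rad,
                 phase = phase, last_lm_angle = last_lm, trial = trial,
                 trial_info = info, n_neurons = n_neu, cfg = cfg),
            class = "spike_session")
}

#' @export
print.spike_session <- function(x, ...) {
  cat(sprintf("spike_session: %d neurons, %d trials of %g s at %g Hz\n",
              x$n_neurons, x$cfg$n_trials, x$cfg$trial_duration,
              x$cfg$sample_rate))
  invisible(x)
}

#' Match LM1a and LM1b trials by approach path
#'
#' Selects pairs of trials, one per hypothesis group, whose egocentric
#' paths just before the second landmark encounter are as similar as
#' possible: pairwise path distance is the summed Euclidean distance
#' between the 2D positions over the last `window` seconds before the
#' encounter, and pairs are chosen greedily (globally smallest distance
#' first, each trial used once) until no pair remains below `max_dist`.
#'
#' @param session a `spike_session`.
#' @param window matching window before the second encounter (s).
#' @param max_dist largest admissible mean per-sample path distance (mm).
#' @param min_trials minimum total number of matched trials required.
#' @return list with `groups` (trial ids: `a`, `b`), `pairs` (data.frame
#'   with the matched pairs and their distances), `window`.
#' @export
matched_trial_subset <- function(session, window = 0.75, max_dist = Inf,
                                 min_trials = 16L) {
  info <- session$trial_info
  fs <- session$cfg$sample_rate
  nw <- round(window * fs)
  seg <- function(tr) {
    i2 <- which(session$trial == tr)[1] + round(info$t_enc2[info$trial == tr] * fs)
    idx <- (i2 - nw + 1):i2
    cbind(session$x[idx], session$y[idx])
  }
  a_ids <- info$trial[info$lm1_type == "a"]
  b_ids <- info$trial[info$lm1_type == "b"]
  if (length(a_ids) == 0 || length(b_ids) == 0)
    stop("matched_trial_subset: a hypothesis group is empty")
  segs <- lapply(seq_len(nrow(info)), function(tr) seg(tr))
  D <- outer(seq_along(a_ids), seq_along(b_ids),
             Vectorize(function(i, j) {
               mean(sqrt(rowSums((segs[[a_ids[i]]] - segs[[b_ids[j]]])^2)))
             }))
  pairs <- data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  Dw <- D
  repeat {
    if (all(!is.finite(Dw)) || min(Dw, na.rm = TRUE) > max_dist) break
    ij <- arrayInd(which.min(Dw), dim(Dw))
    pairs <- rbind(pairs, data.frame(a = a_ids[ij[1]], b = b_ids[ij[2]],
                                     dist = Dw[ij]))
    Dw[ij[1], ] <- Inf
    Dw[, ij[2]] <- Inf
  }
  if (2 * nrow(pairs) < min_trials)
    stop(sprintf("matched_trial_subset: only %d trials matched, need %d",
                 2 * nrow(pairs), min_trials))
  list(groups = list(a = pairs$a, b = pairs$b), pairs = pairs,
       window = window)
}

#' Population state vectors at the second landmark encounter
#'
#' Extracts one state vector per trial from a rate matrix aligned to the
#' second-encounter time (plus an optional offset), for the group-distance
#' analyses.
#'
#' @param session a `spike_session`.
#' @param rates `N_samples x n_neurons` matrix aligned with the session
#'   samples (e.g. filtered rates); defaults to the session's ground-truth
#'   rates.
#' @param trials trial ids to extract.
#' @param offset seconds after the encounter (0 or 0.2).
#' @return matrix `length(trials) x n_neurons`.
#' @export
session_states_at <- function(session, rates = session$rates,
                              trials = session$trial_info$trial,
                              offset = 0) {
  fs <- session$cfg$sample_rate
  info <- session$trial_info
  idx <- vapply(trials, function(tr) {
    which(session$trial == tr)[1] +
      round((info$t_enc2[info$trial == tr] + offset) * fs)
  }, 1)
  idx <- pmin(pmax(idx, 1), nrow(rates))
  rates[idx, , drop = FALSE]
}
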