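#' Draw the velocity input code of a network instance
#'
#' Each of the 10 velocity cells maps velocity linearly from
#' `[-v_max, v_max]` onto its own firing-rate range; the per-cell minimum
#' rate is drawn uniformly from [0, 0.2] and the maximum from [0.8, 1],
#' once per network instantiation, then held fixed.
#'
#' @param cfg a [sim_config()].
#' @return list with numeric vectors `min` and `max` of length `cfg$n_vel`.
#' @export
sample_velocity_code <- function(cfg = sim_config()) {
  list(min = runif(cfg$n_vel, 0, 0.2), max = runif(cfg$n_vel, 0.8, 1))
}

#' Preferred locations of the place-cell grid
#'
#' `z_alpha = (alpha - 1) * 2 * pi / n`, equally tiling the circle. The same
#' grid serves as preferred locations of the landmark map input cells.
#'
#' @param n number of cells.
#' @return numeric vector of angles (rad).
#' @export
place_cell_grid <- function(n = 70L) (seq_len(n) - 1) * 2 * pi / n

#' Encode network inputs for one trial
#'
#' Ten velocity cells carry the noisy velocity (the reported displacement
#' divided by `dt`, clipped to `[-v_max, v_max]`) mapped linearly onto each
#' cell's rate range. The remaining cells carry landmark input, active only
#' at the step of an encounter and the three following steps:
#' * external map: 70 map cells on the place-cell grid with von Mises
#'   activation `r_j = sum_i vm_bump(x_j - l~_i, sigma_w)`, where `l~` is the
#'   noise-rotated map drawn for that encounter;
#' * internal map: one binary cell at activation 1.
#'
#' When two encounter windows overlap, the later encounter's map overwrites
#' from its onset (the agent sees the freshest observation).
#'
#' @param noisy_disp noisy displacements (m) from [corrupt_velocity()].
#' @param encounters an `encounter_log`.
#' @param noisy_maps matrix of per-encounter rotated maps from
#'   [corrupt_map()] (one row per encounter); ignored for the internal map.
#' @param cfg a [sim_config()].
#' @param velocity_code from [sample_velocity_code()].
#' @return `T x n_in` activation matrix.
#' @export
encode_inputs <- function(noisy_disp, encounters, noisy_maps,
                          cfg = sim_config(), velocity_code) {
  T <- length(noisy_disp)
  v_rep <- noisy_disp / cfg$dt
  v_rep <- pmin(pmax(v_rep, -cfg$v_max), cfg$v_max)
  u <- (v_rep + cfg$v_max) / (2 * cfg$v_max)
  Xv <- outer(u, velocity_code$max - velocity_code$min) +
    matrix(velocity_code$min, T, cfg$n_vel, byrow = TRUE)
  if (cfg$scheme == "external_map") {
    Xl <- matrix(0, T, cfg$n_out)
    if (nrow(encounters) > 0) {
      if (is.null(dim(noisy_maps)) || nrow(noisy_maps) < nrow(encounters))
        stop("encode_inputs: need one noisy map per encounter")
      xj <- place_cell_grid(cfg$n_out)
      for (e in seq_len(nrow(encounters))) {
        w <- encounters$t[e]:min(encounters$t[e] + 3L, T)
        r <- colSums(vm_bump(outer(noisy_maps[e, ], xj, "-"), cfg$sigma_w))
        Xl[w, ] <- matrix(r, length(w), cfg$n_out, byrow = TRUE)
      }
    }
  } else {
    Xl <- matrix(0, T, 1)
    for (e in seq_len(nrow(encounters))) {
      Xl[encounters$t[e]:min(encounters$t[e] + 3L, T), 1] <- 1
    }
  }
  cbind(Xv, Xl)
}

#' Place-cell training targets for a trajectory
#'
#' The supervised target at step `t` is a population of `n_out` place cells
#' with von Mises tuning of width `sigma_o` to the true location:
#' `o~_{alpha,t} = vm_bump(z_alpha - y_t, sigma_o)`.
#'
#' @param traj a `trajectory`.
#' @param cfg a [sim_config()].
#' @return `T x n_out` matrix with entries in `(0, 1]`, plus attribute `z`
#'   (the preferred locations).
#' @export
make_targets <- function(traj, cfg = sim_config()) {
  z <- place_cell_grid(cfg$n_out)
  O <- vm_bump(outer(traj$y, z, "-"), cfg$sigma_o)
  attr(O, "z") <- z
  O
}

#' Steps with nonzero landmark input
#'
#' Helper used by several analyses that exclude encounter-input windows.
#'
#' @param encounters an `encounter_log`.
#' @param T trial length in steps.
#' @return logical vector of length `T`.
#' @export
landmark_input_steps <- function(encounters, T) {
  m <- logical(T)
  for (e in seq_len(nrow(encounters)))
    m[encounters$t[e]:min(encounters$t[e] + 3L, T)] <- TRUE
  m
}
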