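#' Simulation configuration for the circular-track task
#'
#' Bundles every constant that defines the task: a simulated agent runs on a
#' circular track of radius 0.5 m for 10 s in timesteps of 0.1 s, among
#' 2-4 perceptually identical landmarks. Velocity information and (in the
#' external-map scheme) the landmark map are corrupted by Gaussian noise.
#'
#' Units: angles and angular thresholds are radians; `v_max`, `sigma_a` and
#' `sigma_v` are metric (m/s, m/s^2, and m per step respectively). Metric
#' displacements convert to angles via `angle = arc / radius`, so the
#' encounter threshold `d_enc = pi/20` rad corresponds to `pi/40` m on the
#' default 0.5 m track.
#'
#' @param dt timestep (s).
#' @param duration trial length (s); `duration/dt` must be integral.
#' @param radius track radius (m).
#' @param v_max speed cap (m/s).
#' @param sigma_a acceleration s.d. (m/s^2).
#' @param a_max acceleration truncation bound (m/s^2).
#' @param delta_sep minimum angular separation between landmarks (rad).
#' @param d_enc encounter ("observation") threshold (rad); an encounter is
#'   triggered when the agent comes within `d_enc` of a landmark different
#'   from the previously encountered one.
#' @param sigma_v velocity-noise s.d., in metres per step.
#' @param sigma_l map-noise s.d. (rad): the whole map is coherently rotated
#'   by a fresh `N(0, sigma_l^2)` draw at each landmark encounter.
#' @param sigma_w tuning width of the landmark map input cells (rad).
#' @param sigma_o tuning width of the place-cell training targets (rad).
#' @param scheme `"external_map"` (the landmark map is an input) or
#'   `"internal_map"` (a single binary landmark-presence input; maps must be
#'   inferred and stored by the agent).
#' @param n_out number of place-cell output targets.
#' @param n_vel number of velocity input cells.
#' @param truncation how to enforce the `a_max` bound on sampled
#'   accelerations: clip to the bound (default) or resample until inside.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, duration = 10, radius = 0.5,
                       v_max = pi / 2, sigma_a = pi / 4, a_max = pi / 2,
                       delta_sep = pi / 9, d_enc = pi / 20,
                       sigma_v = v_max * dt / 10, sigma_l = pi / 50,
                       sigma_w = pi / 6, sigma_o = pi / 6,
                       scheme = c("external_map", "internal_map"),
                       n_out = 70L, n_vel = 10L,
                       truncation = c("clip", "resample")) {
  scheme <- match.arg(scheme)
  truncation <- match.arg(truncation)
  stopifnot(dt > 0, duration > 0, radius > 0, v_max > 0, sigma_a >= 0,
            a_max > 0, delta_sep > 0, d_enc > 0, sigma_v >= 0, sigma_l >= 0,
            sigma_w > 0, sigma_o > 0, n_out >= 2, n_vel >= 1)
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("duration must be an integral number of timesteps")
  if (!(d_enc < delta_sep))
    stop("encounter threshold d_enc must be smaller than landmark separation delta_sep")
  structure(list(
    dt = dt, duration = duration, radius = radius, v_max = v_max,
    sigma_a = sigma_a, a_max = a_max, delta_sep = delta_sep, d_enc = d_enc,
    sigma_v = sigma_v, sigma_l = sigma_l, sigma_w = sigma_w, sigma_o = sigma_o,
    scheme = scheme, n_out = as.integer(n_out), n_vel = as.integer(n_vel),
    truncation = truncation, n_steps = as.integer(round(n_steps))
  ), class = "sim_config")
}

#' Number of input cells for a scheme
#'
#' 80 in the external-map scheme (10 velocity + 70 map cells), 11 in the
#' internal-map scheme (10 velocity + 1 binary landmark-presence cell).
#'
#' @param cfg a [sim_config()].
#' @return integer input dimension.
#' @export
n_input_cells <- function(cfg) {
  if (cfg$scheme == "external_map") cfg$n_vel + cfg$n_out else cfg$n_vel + 1L
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d steps of %.2g s on a %.2g m ring, %s scheme\n",
    x$n_steps, x$dt, x$radius, x$scheme))
  invisible(x)
}
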