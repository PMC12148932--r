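#' Simulate one complete trial
#'
#' Draws (or accepts) an environment and a trajectory, detects landmark
#' encounters, corrupts the velocity signal and (external map) the landmark
#' map, and builds the network input and target matrices.
#'
#' @param cfg a [sim_config()].
#' @param env an `environment_map`; sampled with `K` landmarks if `NULL`.
#' @param traj a `trajectory`; sampled if `NULL`.
#' @param velocity_code from [sample_velocity_code()]; drawn ad hoc if `NULL`.
#' @param K landmark count used when `env` is `NULL` (sampled uniformly from
#'   2:4 if `NULL`, the training distribution).
#' @return a `trial`: list with `env`, `traj`, `encounters`, `noisy_disp`
#'   (m per step), `noisy_maps` (one row per encounter, or `NULL`), `X`
#'   (inputs), `target` (place-cell targets) and `included` (`TRUE` when at
#'   least two different landmarks were encountered).
#' @export
make_trial <- function(cfg = sim_config(), env = NULL, traj = NULL,
                       velocity_code = NULL, K = NULL) {
  if (is.null(env)) {
    if (is.null(K)) K <- sample(2:4, 1)
    env <- sample_environment(K, cfg)
  }
  if (is.null(traj)) traj <- sample_trajectory(cfg)
  if (is.null(velocity_code)) velocity_code <- sample_velocity_code(cfg)
  enc <- detect_encounters(traj, env, cfg)
  nd <- corrupt_velocity(traj, cfg)
  nm <- if (cfg$scheme == "external_map" && nrow(enc) > 0)
    corrupt_map(env, cfg, n = nrow(enc)) else NULL
  X <- encode_inputs(nd, enc, nm, cfg, velocity_code)
  structure(list(env = env, traj = traj, encounters = enc, noisy_disp = nd,
                 noisy_maps = nm, X = X, target = make_targets(traj, cfg),
                 included = nrow(enc) >= 2L),
            class = "trial")
}

#' Generate a batch of trials from a test configuration
#'
#' The five evaluation configurations:
#' 1. the training distribution: random environments with 2-4 landmarks,
#'    random trajectories (internal-map scheme: environment drawn uniformly
#'    from the four fixed maps instead);
#' 2. fixed landmarks `{0, 2*pi/3}` (environment e1), random trajectories;
#' 3. same fixed landmarks, constant speed `v_max/2`, random initial angle
#'    and direction;
#' 4. landmarks `{0, 2*pi/3 + alpha*pi/3}`, `alpha` in `[0, 1]` (drawn
#'    uniformly per trial unless supplied), constant speed;
#' 5. environment e1 or e2 (equal probability per trial), random
#'    trajectories.
#'
#' Trials in which fewer than two different landmarks were encountered carry
#' `included = FALSE` and are flagged for exclusion from error statistics.
#'
#' @param config_id integer 1..5.
#' @param n_trials number of trials.
#' @param cfg a [sim_config()].
#' @param velocity_code shared velocity input code; drawn once if `NULL`.
#' @param alpha fixed landmark offset parameter for configuration 4.
#' @return a `trial_set`: list of `trial` objects with attributes
#'   `config_id` and `velocity_code`.
#' @export
make_experiment <- function(config_id, n_trials, cfg = sim_config(),
                            velocity_code = NULL, alpha = NULL) {
  if (!config_id %in% 1:5) stop("unknown config_id: ", config_id)
  if (is.null(velocity_code)) velocity_code <- sample_velocity_code(cfg)
  one <- function() {
    switch(config_id,
      {
        if (cfg$scheme == "internal_map") {
          env <- fixed_environment(sample(c("e1", "e2", "e3", "e4"), 1))
          make_trial(cfg, env = env, velocity_code = velocity_code)
        } else make_trial(cfg, velocity_code = velocity_code)
      },
      make_trial(cfg, env = fixed_environment("e1"),
                 velocity_code = velocity_code),
      make_trial(cfg, env = fixed_environment("e1"),
                 traj = constant_trajectory(cfg),
                 velocity_code = velocity_code),
      {
        a <- if (is.null(alpha)) runif(1) else alpha
        env <- landmark_environment(c(0, 2 * pi / 3 + a * pi / 3))
        make_trial(cfg, env = env, traj = constant_trajectory(cfg),
                   velocity_code = velocity_code)
      },
      make_trial(cfg, env = fixed_environment(sample(c("e1", "e2"), 1)),
                 velocity_code = velocity_code))
  }
  trials <- replicate(n_trials, one(), simplify = FALSE)
  structure(trials, class = "trial_set", config_id = config_id,
            velocity_code = velocity_code)
}

#' Task-phase labels for the steps of a trial
#'
#' `"LM0"` before the first landmark encounter, `"LM1"` from the first to
#' just before the second, `"LM2"` from the second encounter on (further
#' encounters stay in LM2: location is disambiguated).
#'
#' @param encounters an `encounter_log`.
#' @param T trial length in steps.
#' @return character vector of length `T`.
#' @export
phase_labels <- function(encounters, T) {
  n_seen <- findInterval(seq_len(T), encounters$t)
  c("LM0", "LM1", "LM2")[pmin(n_seen, 2L) + 1L]
}

#' Serialize / load a trial batch
#'
#' Writes one directory per trial (`trial_0001`, ...) containing
#' `trajectory.csv` (`t, a, v, y`), `encounters.csv` (`t, landmark`) and a
#' JSON sidecar with the configuration, the environment and the noisy
#' observations, so a batch can be rebuilt bit-for-bit without rerunning
#' the generator.
#'
#' @param trials a `trial_set` or list of `trial`s.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly (`write_trials`); a `trial_set` (`read_trials`).
#' @export
write_trials <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vc <- attr(trials, "velocity_code")
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    td <- file.path(dir, sprintf("trial_%04d", i))
    dir.create(td, showWarnings = FALSE)
    write.csv(data.frame(t = seq_along(tr$traj$y), a = tr$traj$a,
                         v = tr$traj$v, y = tr$traj$y),
              file.path(td, "trajectory.csv"), row.names = FALSE)
    write.csv(as.data.frame(tr$encounters),
              file.path(td, "encounters.csv"), row.names = FALSE)
    side <- list(y0 = tr$traj$y0, landmarks = tr$env$landmarks,
                 env_id = tr$env$env_id, noisy_disp = tr$noisy_disp,
                 noisy_maps = tr$noisy_maps, included = tr$included)
    jsonlite::write_json(side, file.path(td, "trial.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  jsonlite::write_json(list(n_trials = length(trials),
                            config_id = attr(trials, "config_id"),
                            velocity_code = vc),
                       file.path(dir, "batch.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_trials
#' @param cfg the [sim_config()] the batch was generated under.
#' @export
read_trials <- function(dir, cfg = sim_config()) {
  meta <- jsonlite::read_json(file.path(dir, "batch.json"),
                              simplifyVector = TRUE)
  vc <- meta$velocity_code
  trials <- lapply(seq_len(meta$n_trials), function(i) {
    td <- file.path(dir, sprintf("trial_%04d", i))
    tj <- read.csv(file.path(td, "trajectory.csv"))
    ec <- read.csv(file.path(td, "encounters.csv"))
    side <- jsonlite::read_json(file.path(td, "trial.json"),
                                simplifyVector = TRUE)
    env <- new_environment(side$landmarks, side$env_id)
    traj <- new_trajectory(tj$a, tj$v, tj$y, side$y0)
    enc <- structure(data.frame(t = as.integer(ec$t),
                                landmark = as.integer(ec$landmark)),
                     class = c("encounter_log", "data.frame"))
    nm <- side$noisy_maps
    if (!is.null(nm)) nm <- matrix(unlist(nm), nrow = nrow(enc), byrow = FALSE)
    X <- encode_inputs(side$noisy_disp, enc, nm, cfg, vc)
    structure(list(env = env, traj = traj, encounters = enc,
                   noisy_disp = side$noisy_disp, noisy_maps = nm, X = X,
                   target = make_targets(traj, cfg),
                   included = isTRUE(side$included)),
              class = "trial")
  })
  structure(trials, class = "trial_set", config_id = meta$config_id,
            velocity_code = vc)
}
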