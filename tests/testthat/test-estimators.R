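cfg <- sim_config()

enc_log <- function(t, lm) {
  structure(data.frame(t = as.integer(t), landmark = as.integer(lm)),
            class = c("encounter_log", "data.frame"))
}

test_that("path integration with correction integrates, snaps and tie-breaks", {
  env <- fixed_environment("e1")
  T <- cfg$n_steps
  # zero noise, start at 0, no encounters: exact tracking
  set.seed(20)
  traj <- constant_trajectory(cfg, y0 = 0, direction = 1)
  cfg0 <- sim_config(sigma_v = 0)
  est <- path_integrate_correct(traj$v * cfg$dt, enc_log(c(), c()), env, cfg0)
  expect_equal(localization_error(est, traj), 0, ignore_attr = TRUE)
  # estimate at 0.5 rad at an encounter snaps to landmark 1 (0.5 < 1.594)
  d0 <- c(0.5 * cfg$radius, rep(0, T - 1))
  est <- path_integrate_correct(d0, enc_log(2, 1), env, cfg0)
  expect_equal(est$y_hat[1], 0.5)
  expect_equal(est$y_hat[2], 0)
  # exactly midway between the two landmarks: lowest-index landmark wins
  # (landmarks at binary-exact angles 0.75 and 1.25, estimate at 1.0, so
  # both circular distances are bit-identical 0.25)
  env_tie <- landmark_environment(c(0.75, 1.25))
  dtie <- c(1.0 * cfg$radius, rep(0, T - 1))
  est <- path_integrate_correct(dtie, enc_log(2, 1), env_tie, cfg0)
  expect_equal(est$y_hat[2], 0.75)
})

test_that("effective sample size and systematic resampling behave", {
  # N_eff trivia
  w_eq <- rep(1 / 100, 100)
  expect_equal(1 / sum(w_eq^2), 100)
  w_one <- c(1, rep(0, 99))
  expect_equal(1 / sum(w_one^2), 1)
  # resampling preserves the weighted mean in expectation
  set.seed(21)
  y <- runif(50, 0, 1)
  w <- runif(50); w <- w / sum(w)
  target <- sum(w * y)
  means <- replicate(1000, mean(y[systematic_resample(w)]))
  expect_equal(mean(means), target, tolerance = 0.01)
  # every index returned is valid and frequencies track the weights
  idx <- systematic_resample(c(0.5, 0.25, 0.25), u = 0.001)
  expect_true(all(idx %in% 1:3))
  big_idx <- systematic_resample(rep(c(0.7, 0.3) / 100, c(100, 100))[1:200] /
                                   sum(rep(c(0.7, 0.3) / 100, c(100, 100))[1:200]))
  expect_length(big_idx, 200)
})

test_that("particle weights stay normalized through every update", {
  set.seed(22)
  tr <- make_trial(cfg, env = fixed_environment("e1"))
  for (enh in c(FALSE, TRUE)) {
    run <- pf_run(tr$noisy_disp, tr$encounters, tr$noisy_maps, tr$env, cfg,
                  filter_config(N_p = 300, enhanced = enh),
                  keep_particles = TRUE)
    sums <- vapply(run$history, function(h) sum(h$w), 0)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("with no noise and a known start every agent tracks exactly", {
  # landmark-correction is exact only when encounters happen exactly at
  # landmark coordinates: at speed v_max/2 each step is pi/20 rad, so with
  # landmarks at {0, pi}, start 0 and threshold pi/40 every encounter
  # coincides with a landmark
  cfg0 <- sim_config(sigma_v = 0, sigma_l = 0, d_enc = pi / 40)
  env <- landmark_environment(c(0, pi))
  set.seed(23)
  traj <- constant_trajectory(cfg0, y0 = 0, direction = 1)
  enc <- detect_encounters(traj, env, cfg0)
  expect_gte(nrow(enc), 2)
  expect_true(all(circ_dist(traj$y[enc$t],
                            env$landmarks[enc$landmark]) < 1e-9))
  disp <- traj$v * cfg0$dt
  est_pi <- path_integrate_correct(disp, enc, env, cfg0)
  expect_lt(localization_error(est_pi, traj), 1e-10)
  run <- pf_run(disp, enc, NULL, env, cfg0, filter_config(N_p = 100),
                init = 0)
  expect_lt(localization_error(run$est, traj), 1e-10)
})

test_that("after one encounter in a two-landmark world the posterior is bimodal", {
  set.seed(24)
  env <- fixed_environment("e1")
  # keep only trials whose first encounter leaves time to look at LM1
  trials <- make_experiment(2, 10, cfg)
  checked <- 0
  for (tr in trials) {
    if (nrow(tr$encounters) < 2) next
    t1 <- tr$encounters$t[1]; t2 <- tr$encounters$t[2]
    if (t2 - t1 < 6) next
    run <- pf_run(tr$noisy_disp, tr$encounters, tr$noisy_maps, tr$env, cfg,
                  filter_config(N_p = 2000), keep_particles = TRUE)
    h <- run$history[[t1 + 5]]  # mid-LM1
    dens <- ref_particle_kde(h$y, h$w, place_cell_grid(70), bw = pi / 25)
    bumps <- find_bumps(dens, threshold = max(dens) / 4, min_sep = 5)
    expect_equal(length(bumps), 2)
    sep <- circ_dist(place_cell_grid(70)[bumps[1]],
                     place_cell_grid(70)[bumps[2]])
    expect_equal(sep, 2 * pi / 3, tolerance = 0.1)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("enhanced pruning removes only particles expecting a missed landmark", {
  env <- fixed_environment("e1")
  cfgq <- sim_config(sigma_v = 0)
  T <- cfgq$n_steps
  # agent parked at landmark 1; particles split between both landmarks
  disp <- rep(0, T)
  enc <- enc_log(1, 1)
  set.seed(25)
  run <- pf_run(disp, enc, NULL, env, cfgq,
                filter_config(N_p = 1000, enhanced = TRUE),
                keep_particles = TRUE)
  # both hypothesis clusters survive: neither is "a different landmark"
  # from its own last encounter
  h <- run$history[[T]]
  dens <- ref_particle_kde(h$y, h$w, place_cell_grid(70), bw = pi / 25)
  bumps <- find_bumps(dens, threshold = max(dens) / 4, min_sep = 5)
  expect_equal(length(bumps), 2)
})

test_that("enhanced filter disambiguates by the absence of an encounter", {
  # agent starts just past landmark 2 travelling CCW through the long gap.
  # The wrong hypothesis (that the first encounter was landmark 1) implies
  # passing landmark 2 again about 2*pi/3 rad later -- but no encounter
  # happens there, so the enhanced filter prunes the wrong cluster mid-gap
  # while the basic filter stays bimodal until the next true encounter.
  env <- fixed_environment("e1")
  cfgq <- sim_config(sigma_v = 1e-6)
  set.seed(26)
  # start just short of landmark 2 so the first recorded step falls
  # inside its observation zone, then travel CCW through the long gap
  traj <- constant_trajectory(cfgq, y0 = wrap_angle(2 * pi / 3 - 0.05),
                              direction = 1)
  enc <- detect_encounters(traj, env, cfgq)
  expect_equal(enc$landmark[1:2], c(2L, 1L))
  disp <- traj$v * cfgq$dt
  run_b <- pf_run(disp, enc, NULL, env, cfgq, filter_config(N_p = 1000))
  run_e <- pf_run(disp, enc, NULL, env, cfgq,
                  filter_config(N_p = 1000, enhanced = TRUE))
  t2 <- enc$t[2]
  window <- (t2 - 8):(t2 - 1)  # late LM1, well after the wrong cluster
                               # should have passed the silent landmark zone
  err_b <- localization_error(run_b$est, traj, window = window)
  err_e <- localization_error(run_e$est, traj, window = window)
  expect_lt(err_e, err_b)
  expect_lt(err_e, 0.3)
})

test_that("grid oracle conserves mass and stays uniform without information", {
  cfg0 <- sim_config(sigma_v = 0)
  T <- cfg0$n_steps
  set.seed(27)
  traj <- sample_trajectory(cfg0)
  out <- grid_bayes_oracle(traj$v * cfg0$dt, enc_log(c(), c()), NULL,
                           fixed_environment("e1"), cfg0, grid_bins = 180)
  expect_equal(rowSums(out$posterior), rep(1, T))
  expect_true(max(abs(out$posterior - 1 / 180)) < 1e-9)
  # with noise, mass still sums to one at every step
  set.seed(27)
  tr <- make_trial(cfg, env = fixed_environment("e1"))
  out <- grid_bayes_oracle(tr$noisy_disp, tr$encounters, tr$noisy_maps,
                           tr$env, cfg)
  expect_equal(rowSums(out$posterior), rep(1, T))
})

test_that("particle cloud matches the exact posterior on a small instance", {
  set.seed(28)
  found <- FALSE
  for (i in 1:10) {
    tr <- make_trial(cfg, env = fixed_environment("e1"),
                     traj = constant_trajectory(cfg))
    if (nrow(tr$encounters) >= 2) { found <- TRUE; break }
  }
  expect_true(found)
  gb <- grid_bayes_oracle(tr$noisy_disp, tr$encounters, tr$noisy_maps,
                          tr$env, cfg, grid_bins = 360)
  run <- pf_run(tr$noisy_disp, tr$encounters, tr$noisy_maps, tr$env, cfg,
                filter_config(N_p = 10000), keep_particles = TRUE)
  # total-variation distance between the KDE of the cloud and the exact
  # posterior, after the first encounter
  for (t in c(tr$encounters$t[1] + 2, tr$encounters$t[2] + 2)) {
    h <- run$history[[t]]
    kde <- ref_particle_kde(h$y, h$w, gb$theta, bw = cfg$sigma_l)
    smooth_post <- ref_particle_kde(gb$theta, gb$posterior[t, ], gb$theta,
                                    bw = cfg$sigma_l)
    tv <- 0.5 * sum(abs(kde - smooth_post))
    expect_lt(tv, 0.1)
  }
})

test_that("after disambiguation the particle filter tracks the exact posterior mean", {
  # once the posterior is unimodal (LM2) the weighted circular mean of
  # 1000 particles agrees with the exact grid posterior to < 0.05 rad;
  # during the bimodal LM1 phase the mean is mode-mass sensitive and
  # fluctuates with Monte-Carlo error, which the kernel-density/TV check
  # above covers instead
  set.seed(301)
  cfg <- sim_config()
  agree <- c()
  for (i in 1:12) {
    tr <- make_trial(cfg, env = fixed_environment("e1"),
                     traj = constant_trajectory(cfg))
    if (nrow(tr$encounters) < 2) next
    gb <- grid_bayes_oracle(tr$noisy_disp, tr$encounters, tr$noisy_maps,
                            tr$env, cfg)
    run <- pf_run(tr$noisy_disp, tr$encounters, tr$noisy_maps, tr$env, cfg,
                  filter_config(N_p = 1000))
    lm2 <- seq_len(cfg$n_steps) > tr$encounters$t[2]
    agree <- c(agree,
               circ_dist(run$est$y_hat[lm2], gb$est$y_hat[lm2]) < 0.05)
  }
  expect_gt(length(agree), 100)
  expect_gte(mean(agree), 0.95)
})

test_that("localization error reduces to its analytic extremes", {
  set.seed(29)
  traj <- sample_trajectory(cfg)
  perfect <- structure(data.frame(t = seq_along(traj$y), y_hat = traj$y,
                                  circ_var = 0, agent = "x"),
                       class = c("estimate_trace", "data.frame"))
  expect_equal(localization_error(perfect, traj), 0, ignore_attr = TRUE)
  # independent uniform estimates against uniform truth: pi/2 on average
  cfgL <- sim_config(duration = 4000, sigma_a = 0)
  trajL <- sample_trajectory(cfgL)
  unif <- structure(data.frame(t = seq_along(trajL$y),
                               y_hat = runif(length(trajL$y), 0, 2 * pi),
                               circ_var = 0, agent = "x"),
                    class = c("estimate_trace", "data.frame"))
  expect_equal(as.numeric(localization_error(unif, trajL)), pi / 2,
               tolerance = 0.05)
  # undefined estimates are excluded and counted
  half <- perfect
  half$y_hat[1:10] <- NA
  e <- localization_error(half, traj)
  expect_equal(attr(e, "n_undefined"), 10)
  expect_equal(as.numeric(e), 0)
})
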