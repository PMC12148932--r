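test_that("entropy relative to uniform reproduces its worked examples", {
  expect_equal(entropy_rel_uniform(c(1, 0)), 1, tolerance = 1e-6)
  expect_equal(entropy_rel_uniform(c(1, 1, 0, 0)), 1, tolerance = 1e-6)
  expect_equal(round(entropy_rel_uniform(c(1, 1, 1, 1.3)), 2), 0.01)
  # uniform histograms of any size carry zero relative entropy
  for (n in c(2, 5, 64)) {
    expect_equal(entropy_rel_uniform(rep(3.7, n)), 0)
  }
  # a single occupied bin carries log2(n) bits
  expect_equal(entropy_rel_uniform(c(5, rep(0, 63))), 6, tolerance = 1e-6)
  # permutation invariance
  set.seed(60)
  h <- rexp(16)
  expect_equal(entropy_rel_uniform(h), entropy_rel_uniform(sample(h)))
  expect_error(entropy_rel_uniform(numeric(0)), "empty")
  expect_error(entropy_rel_uniform(c(1, -1)), "nonnegative")
})

test_that("causal low-pass filtering is causal and calibrated", {
  fs <- 100
  n <- 4000
  # constant-rate Poisson spikes: filtered rate approaches the true rate
  set.seed(61)
  counts <- matrix(rpois(n, 8 / fs), n, 1)
  rt <- lowpass_rates(counts, cutoff = 1, order = 1, sample_rate = fs)
  expect_equal(mean(rt$rates[-(1:500), 1]), 8, tolerance = 0.2)
  # impulse response: zero before the impulse (causality), decay after
  imp <- matrix(0, 400, 1); imp[200, 1] <- 1
  ri <- lowpass_rates(imp, cutoff = 1, order = 1, sample_rate = fs)
  expect_true(all(abs(ri$rates[1:199, 1]) < 1e-12))
  pk <- which.max(ri$rates[, 1])
  post <- ri$rates[pk:(pk + 60), 1]
  expect_true(all(diff(post) <= 1e-12))  # monotone decay from the peak
  expect_true(all(post > 0))
  # zero spikes give zero rates; cutoff above Nyquist errors
  expect_true(all(lowpass_rates(matrix(0, 100, 2), 1,
                                sample_rate = fs)$rates == 0))
  expect_error(lowpass_rates(counts, cutoff = 60, sample_rate = fs),
               "Nyquist")
})

test_that("spatial maps count occupancy and score spatial information", {
  set.seed(62)
  n <- 8000
  x <- runif(n, -250, 250); y <- runif(n, -250, 250)
  # uniform rate: near-zero map entropy
  rates <- cbind(rep(2, n), rep(0, n))
  sm <- spatial_maps(rates, x, y, arena_radius = 250, grid = 8)
  expect_equal(sum(sm$occupancy), n)
  expect_equal(spatial_map_entropy(sm$maps[1, ]), 0, tolerance = 1e-6)
  # rate concentrated in exactly one of 64 visited bins: 6 bits
  bx <- findInterval(x, seq(-250, 250, length.out = 9), all.inside = TRUE)
  by <- findInterval(y, seq(-250, 250, length.out = 9), all.inside = TRUE)
  rates2 <- cbind(as.numeric(bx == 3 & by == 5))
  sm2 <- spatial_maps(rates2, x, y, arena_radius = 250, grid = 8)
  expect_equal(spatial_map_entropy(sm2$maps[1, ]), 6, tolerance = 1e-6)
})

test_that("map distances separate remapping from stability", {
  set.seed(63)
  n <- 24000
  t <- (seq_len(n) - 1) / 100
  x <- runif(n, -250, 250); y <- runif(n, -250, 250)
  cond <- rep(c("A", "B"), each = n / 2)
  # neuron 1 remaps between conditions; neuron 2 is stable
  f1 <- exp(-((x - 100)^2 + y^2) / 1e4)
  f1b <- exp(-((x + 100)^2 + (y - 80)^2) / 1e4)
  stable <- exp(-(x^2 + (y + 120)^2) / 1e4)
  rates <- cbind(ifelse(cond == "A", f1, f1b), stable)
  r <- map_distance_test(rates, x, y, t, cond, "A", "B",
                         arena_radius = 250, segment = 30, n_boot = 200)
  expect_gt(r$across[1], r$within_a[1] + r$within_b[1])  # remapper
  expect_lt(r$across[2], 0.5 * r$across[1])              # stable cell
  # identical maps: zero distance
  m <- spatial_maps(rates, x, y, 250)$maps
  ok <- !is.na(m[1, ])
  expect_equal(sqrt(sum((m[1, ok] - m[1, ok])^2)), 0)
})

test_that("the categorical linear decoder separates separable states", {
  set.seed(64)
  n_tr <- 30; per <- 40
  trial <- rep(seq_len(n_tr), each = per)
  labels <- rep(rep(c("LM0", "LM1", "LM2"), times = c(10, 10, 20)), n_tr)
  mu <- cbind(LM0 = c(1, 0, 0), LM1 = c(0, 1, 0), LM2 = c(0, 0, 1))
  rates <- t(mu[, labels]) + matrix(rnorm(n_tr * per * 3, 0, 0.1),
                                    n_tr * per, 3)
  d <- phase_decoder(rates, labels, trial, test_trials = 1:6)
  expect_gt(d$accuracy, 0.97)
  expect_equal(dim(d$W), c(4, 3))  # (n_neurons + 1) x 3 parameters
  # shuffled labels fall to chance
  acc_sh <- phase_decoding_accuracy(rates, sample(labels), trial, n_folds = 5)
  expect_lt(abs(acc_sh - 1 / 3), 0.1)
  # missing class in training errors
  expect_error(phase_decoder(rates[labels != "LM2", ],
                             labels[labels != "LM2"],
                             trial[labels != "LM2"], test_trials = 1),
               "absent")
})

test_that("pairwise correlations and their preservation behave at extremes", {
  set.seed(65)
  n <- 6000
  lab <- rep(c("LM1", "LM2"), each = n / 2)
  shared <- sin(seq_len(n) / 50)
  # duplicated neuron pair: correlation 1 in every phase
  r1 <- shared + rnorm(n, 0, 0.01)
  rates <- cbind(r1, r1, rnorm(n), rnorm(n))
  pc <- pairwise_correlations(rates, lab, phases = c("LM1", "LM2"))
  expect_equal(pc$matrices$LM1[1, 2], 1, tolerance = 0.01)
  expect_equal(pc$matrices$LM2[1, 2], 1, tolerance = 0.01)
  # independent white-noise population: correlation of correlations near 0
  set.seed(66)
  w <- matrix(rnorm(n * 20), n, 20)
  pcw <- pairwise_correlations(w, lab, phases = c("LM1", "LM2"))
  expect_lt(abs(pcw$corr_of_corr$corr_of_corr[1]), 0.2)
  # a fixed loading structure across phases is preserved
  set.seed(67)
  L <- matrix(rnorm(20 * 3), 20, 3)
  Z <- matrix(rnorm(n * 3), n, 3)
  rs <- Z %*% t(L) + matrix(rnorm(n * 20, 0, 0.5), n, 20)
  pcs <- pairwise_correlations(rs, lab, phases = c("LM1", "LM2"))
  expect_gt(pcs$corr_of_corr$corr_of_corr[1], 0.8)
  # silent neurons are excluded and reported
  rates_s <- cbind(rates, 0)
  pcs2 <- pairwise_correlations(rates_s, lab, phases = c("LM1", "LM2"))
  expect_equal(pcs2$n_excluded, 1)
})

test_that("cross-population rate prediction transfers structure", {
  # a shared slow latent drives all neurons throughout a 50-min session
  # (the autocorrelated, band-passed rates leave few effective samples,
  # so real-session durations are needed for the 88-column lasso)
  set.seed(68)
  fs <- 100; n <- 3e5
  z <- as.numeric(stats::filter(rnorm(n), rep(1, 300) / sqrt(300),
                                sides = 1))
  z[is.na(z)] <- 0
  load <- runif(12, 0.5, 2)
  counts <- matrix(rpois(n * 12, pmax(outer(z, load) * 8 + 25, 0.1) / fs),
                   n, 12)
  rt <- bandpass_rates(counts, sample_rate = fs)
  nk <- nrow(rt$rates)
  # condition blocks: train, a held-out block in the same condition, and
  # a temporally distant block standing for the other condition
  lab <- rep("far", nk)
  lab[1:floor(0.35 * nk)] <- "train"
  lab[floor(0.4 * nk):floor(0.5 * nk)] <- "near"
  rw <- rate_prediction_r2(rt, lab, target_neuron = 1,
                           phase_train = "train", phase_test = "near")
  ra <- rate_prediction_r2(rt, lab, target_neuron = 1,
                           phase_train = "train", phase_test = "far")
  expect_gt(rw$r2, 0.4)
  # frozen coefficients transfer across condition blocks when the
  # underlying structure is shared
  expect_gt(ra$r2, 0.75 * rw$r2)
  # duplicating the target among the predictors makes it predictable
  # almost perfectly
  counts_dup <- counts
  counts_dup[, 2] <- counts[, 1]
  rtd <- bandpass_rates(counts_dup, sample_rate = fs)
  rd <- rate_prediction_r2(rtd, lab, target_neuron = 1,
                           phase_train = "train", phase_test = "far")
  expect_gt(rd$r2, 0.95)
  # a target independent of the predictors is not predictable
  counts0 <- counts
  counts0[, 1] <- rpois(n, 25 / fs)
  rt0 <- bandpass_rates(counts0, sample_rate = fs)
  r0 <- rate_prediction_r2(rt0, lab, target_neuron = 1,
                           phase_train = "train", phase_test = "far")
  expect_lt(r0$r2, 0.1)
})

test_that("group distances separate distinct clouds and not identical ones", {
  set.seed(70)
  g <- rep(c("a", "b"), each = 12)
  # disjoint supports: separated CIs
  st <- rbind(matrix(rnorm(12 * 5, 0), 12, 5), matrix(rnorm(12 * 5, 6), 12, 5))
  r <- group_distance_test(st, g, n_boot = 500)
  expect_gt(r$across, r$within)
  expect_true(r$separated)
  # identical distributions: CIs overlap
  st0 <- matrix(rnorm(24 * 5), 24, 5)
  r0 <- group_distance_test(st0, g, n_boot = 500)
  expect_false(r0$separated)
  expect_error(group_distance_test(st[1:3, ], c("a", "a", "b")), "2 trials")
})

test_that("window distance correlations track rate smoothness", {
  set.seed(71)
  s <- synth_session(session_config(n_neurons = 30, n_trials = 14,
                                    trial_duration = 8, latent_tau = 2,
                                    phase_gain = 0.5, pos_gain = 0,
                                    base_rate = 20))
  wd <- window_distance_correlation(s, window = 0.75, max_offset = 1.5,
                                    step = 0.75, n_shuffle = 30,
                                    n_boot = 200)
  # full-overlap window reproduces the baseline distances exactly
  expect_equal(wd$R[wd$offset == -0.75], 1, tolerance = 1e-9)
  # smooth latents keep trial distances correlated at positive offsets
  expect_gt(wd$R[wd$offset == 0.75], 0)
  expect_error(window_distance_correlation(s, trials = 1:2), "3 trials")
})

test_that("frame tuning entropy distinguishes reference frames", {
  set.seed(72)
  s <- synth_session(session_config(n_neurons = 6, n_trials = 16,
                                    trial_duration = 8, pos_gain = 0,
                                    phase_gain = 0, base_rate = 10))
  # overwrite rates: neuron 1 tuned to landmark-relative angle, neuron 2
  # tuned to the global angle, neuron 3 untuned
  rel <- circ_diff(s$angle, ifelse(is.na(s$last_lm_angle), 0, s$last_lm_angle))
  rates <- cbind(2 + 2 * cos(rel), 2 + 2 * cos(s$angle), rep(2, length(rel)),
                 matrix(2, length(rel), 3))
  fg <- frame_tuning_entropy(s, rates, frame = "global")
  fr <- frame_tuning_entropy(s, rates, frame = "relative")
  e_rel <- tapply(fr$entropy, fr$neuron, mean)
  e_glo <- tapply(fg$entropy, fg$neuron, mean)
  expect_gt(e_rel[1], e_glo[1])      # landmark-frame cell
  expect_gt(e_glo[2], e_rel[2])      # global-frame cell
  expect_lt(e_glo[3], 0.05)          # untuned: near zero everywhere
  expect_lt(e_rel[3], 0.05)
  # equal sample counts enforced across the two phases
  expect_equal(sum(fr$phase == "LM1"), sum(fr$phase == "LM2"))
})

test_that("eigenvalue spectra expose shared dimensionality against shuffles", {
  set.seed(73)
  n <- 8000
  # rank-1 population: first normalized eigenvalue is 1
  z <- rnorm(n)
  r1 <- outer(z, runif(10, 0.5, 2))
  sp <- pca_spectrum(r1, n_shuffle = 10)
  expect_equal(sp$spectrum[1], 1, tolerance = 1e-9)
  # white noise: spectrum statistically at the shuffle control
  w <- matrix(rnorm(n * 15), n, 15)
  spw <- pca_spectrum(w, n_shuffle = 10)
  expect_lte(spw$n_significant, 2)
  expect_equal(spw$spectrum[8], spw$control[8], tolerance = 0.1)
})
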