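#' Causal low-pass filtered firing rates
#'
#' Bins spikes at the session sample rate (the session's count matrix) and
#' applies a causal Butterworth low-pass filter per neuron. Defaults follow
#' the per-analysis conventions: 1 Hz single-pole for position decoding and
#' pairwise correlations, 0.05 Hz for phase decoding, 0.5 Hz third-order
#' for rate-dispersion and dimensionality analyses.
#'
#' @param session a `spike_session`, or an `N x n_neurons` count matrix.
#' @param cutoff low-pass cutoff (Hz); must be below Nyquist.
#' @param order filter order (1 = single-pole).
#' @param sample_rate required when `session` is a bare matrix.
#' @param clip clip negative filter output to zero.
#' @return a `rate_trace`: list with `rates` (Hz), `cutoff`, `order`,
#'   `sample_rate`.
#' @export
lowpass_rates <- function(session, cutoff = 1, order = 1L,
                          sample_rate = NULL, clip = FALSE) {
  counts <- if (inherits(session, "spike_session")) session$counts else session
  fs <- if (inherits(session, "spike_session"))
    session$cfg$sample_rate else sample_rate
  if (is.null(fs)) stop("sample_rate required for a bare count matrix")
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  r <- counts * fs
  filt <- apply(r, 2, function(col)
    as.numeric(signal::filter(bf, col)))
  if (clip) filt[filt < 0] <- 0
  structure(list(rates = filt, cutoff = cutoff, order = order,
                 sample_rate = fs), class = "rate_trace")
}

#' Causal band-pass filtered and subsampled rates
#'
#' The preprocessing of the cross-population rate-prediction analysis:
#' third-order Butterworth band-pass (default 0.01-0.5 Hz) followed by
#' subsampling to approximately `target_rate`.
#'
#' @inheritParams lowpass_rates
#' @param band two-element passband (Hz).
#' @param target_rate output sampling rate (Hz); samples are decimated by
#'   `round(fs / target_rate)`.
#' @return a `rate_trace` with an extra `keep` element, the indices of the
#'   retained samples in the original timebase.
#' @export
bandpass_rates <- function(session, band = c(0.01, 0.5), order = 3L,
                           target_rate = 3.3, sample_rate = NULL) {
  counts <- if (inherits(session, "spike_session")) session$counts else session
  fs <- if (inherits(session, "spike_session"))
    session$cfg$sample_rate else sample_rate
  if (is.null(fs)) stop("sample_rate required for a bare count matrix")
  if (band[2] >= fs / 2) stop("upper band edge must be below Nyquist")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  r <- counts * fs
  filt <- apply(r, 2, function(col) as.numeric(signal::filter(bf, col)))
  dec <- max(1L, round(fs / target_rate))
  keep <- seq(1L, nrow(filt), by = dec)
  structure(list(rates = filt[keep, , drop = FALSE], cutoff = band,
                 order = order, sample_rate = fs / dec, keep = keep),
            class = "rate_trace")
}

#' Histogram entropy relative to uniform
#'
#' Shannon entropy of a (sum-normalized) histogram in bits, reported
#' relative to a uniform histogram of the same size:
#' `H^(X) = -(H(X) - H(uniform)) = log2(n) - H(X)`. Zero for a uniform
#' histogram, `log2(n)` bits for a single occupied bin. When zeros appear,
#' a small offset (`1e-10`) is added to every bin before normalizing.
#' Invariant under permutation of the bins. Worked examples:
#' `entropy_rel_uniform(c(1, 0))` and `entropy_rel_uniform(c(1, 1, 0, 0))`
#' are both 1 bit, and `entropy_rel_uniform(c(1, 1, 1, 1.3))` is about
#' 0.01 bit.
#'
#' @param h nonnegative histogram (any positive sum).
#' @param offset value added to all bins when any bin is zero.
#' @return entropy relative to uniform (bits).
#' @export
entropy_rel_uniform <- function(h, offset = 1e-10) {
  if (length(h) == 0) stop("empty histogram")
  if (any(h < 0) || !all(is.finite(h))) stop("histogram must be nonnegative")
  if (any(h == 0)) h <- h + offset
  p <- h / sum(h)
  H <- -sum(p * log2(p))
  log2(length(h)) - H
}

#' Spatial firing-rate maps
#'
#' Mean rate of each neuron on a `grid x grid` partition of the square
#' bounding the arena, with per-bin occupancy. Unvisited bins are `NA`.
#' The spatial information of a map is summarized by
#' [entropy_rel_uniform()] of the visited-bin rate histogram via
#' `spatial_map_entropy()`.
#'
#' @param rates `N x n_neurons` rate matrix.
#' @param x,y positions (mm), length `N`.
#' @param arena_radius arena radius (mm); the grid spans `[-r, r]`.
#' @param grid bins per side.
#' @param select optional logical row filter (e.g. one task phase).
#' @return a `spatial_map_set`: list with `maps` (`n_neurons x grid^2`
#'   matrix of mean rates, `NA` when unvisited), `occupancy` (`grid^2`),
#'   `grid`.
#' @export
spatial_maps <- function(rates, x, y, arena_radius, grid = 8L,
                         select = NULL) {
  if (!is.null(select)) {
    rates <- rates[select, , drop = FALSE]
    x <- x[select]; y <- y[select]
  }
  stopifnot(nrow(rates) == length(x), length(x) == length(y))
  edges <- seq(-arena_radius, arena_radius, length.out = grid + 1)
  bx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(y, edges, rightmost.closed = TRUE, all.inside = TRUE)
  bin <- (by - 1L) * grid + bx
  occ <- tabulate(bin, grid^2)
  maps <- matrix(NA_real_, ncol(rates), grid^2)
  for (k in which(occ > 0)) {
    maps[, k] <- colMeans(rates[bin == k, , drop = FALSE])
  }
  structure(list(maps = maps, occupancy = occ, grid = grid),
            class = "spatial_map_set")
}

#' @rdname spatial_maps
#' @param map one row of a `spatial_map_set` `maps` matrix (a 64-element
#'   map vector).
#' @export
spatial_map_entropy <- function(map) {
  entropy_rel_uniform(map[!is.na(map)])
}

#' Distance between spatial maps, across versus within conditions
#'
#' Euclidean distance between per-neuron map vectors (bins unvisited in
#' either map are omitted), comparing two conditions against split-half
#' controls within each condition. Halves are built from nonoverlapping
#' time segments (default 60 s) assigned alternately.
#'
#' @param rates `N x n_neurons` rate matrix.
#' @param x,y,t positions (mm) and times (s) per sample.
#' @param labels condition label per sample.
#' @param cond_a,cond_b the two condition labels to compare.
#' @param arena_radius,grid as in [spatial_maps()].
#' @param segment segment length (s) for the split-half control.
#' @param n_boot bootstrap resamples (over neurons) for the CIs.
#' @param conf confidence level.
#' @return list with per-neuron distance vectors `across`, `within_a`,
#'   `within_b` (`NA` when no jointly visited bins; excluded counts
#'   reported), means and percentile CIs.
#' @export
map_distance_test <- function(rates, x, y, t, labels, cond_a, cond_b,
                              arena_radius, grid = 8L, segment = 60,
                              n_boot = 1000L, conf = 0.95) {
  half_of <- (floor(t / segment) %% 2L) + 1L
  mk <- function(cond, half = NULL) {
    sel <- labels == cond
    if (!is.null(half)) sel <- sel & half_of == half
    spatial_maps(rates, x, y, arena_radius, grid, select = sel)$maps
  }
  a1 <- mk(cond_a, 1); a2 <- mk(cond_a, 2)
  b1 <- mk(cond_b, 1); b2 <- mk(cond_b, 2)
  pair_dist <- function(m1, m2) {
    vapply(seq_len(nrow(m1)), function(i) {
      ok <- !is.na(m1[i, ]) & !is.na(m2[i, ])
      if (!any(ok)) return(NA_real_)
      sqrt(sum((m1[i, ok] - m2[i, ok])^2))
    }, 0)
  }
  across <- (pair_dist(a1, b2) + pair_dist(a2, b1)) / 2
  within_a <- pair_dist(a1, a2)
  within_b <- pair_dist(b1, b2)
  ci <- function(v) {
    v <- v[!is.na(v)]
    bs <- vapply(seq_len(n_boot), function(i)
      mean(sample(v, replace = TRUE)), 0)
    quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  }
  list(across = across, within_a = within_a, within_b = within_b,
       mean_across = mean(across, na.rm = TRUE),
       mean_within = mean(c(within_a, within_b), na.rm = TRUE),
       ci_across = ci(across), ci_within = ci(c(within_a, within_b)),
       n_excluded = sum(is.na(across)))
}

#' Categorical linear decoding of the landmark state
#'
#' A categorical linear decoder with dummy-variable coding:
#' `(n_neurons + 1) x 3` parameters fit by least squares onto the one-hot
#' encoded state {LM0, LM1, LM2}, predicting the argmax class per
#' timepoint. Training data are balanced across the three classes by
#' subsampling; held-out trials never enter training.
#'
#' @param rates `N x n_neurons` rate matrix (filter at 0.05 Hz for the
#'   standard phase-decoding setting).
#' @param labels state label per sample (LM1a/LM1b are merged into LM1).
#' @param trial trial index per sample.
#' @param test_trials trial ids held out for evaluation.
#' @return list with `predicted` (labels for the held-out samples), `truth`,
#'   `accuracy`, and the weight matrix `W`.
#' @export
phase_decoder <- function(rates, labels, trial, test_trials) {
  labels <- sub("^LM1[ab]$", "LM1", labels)
  classes <- c("LM0", "LM1", "LM2")
  if (!all(labels %in% classes)) stop("labels must be LM0/LM1(a/b)/LM2")
  is_test <- trial %in% test_trials
  tr_idx <- which(!is_test)
  if (length(unique(labels[tr_idx])) < 3)
    stop("a class is absent from the training data")
  n_min <- min(table(labels[tr_idx]))
  bal <- unlist(lapply(classes, function(cl) {
    i <- tr_idx[labels[tr_idx] == cl]
    if (length(i) > n_min) sample(i, n_min) else i
  }))
  Ytr <- outer(labels[bal], classes, "==") + 0
  Xtr <- cbind(1, rates[bal, , drop = FALSE])
  W <- lm.fit(Xtr, Ytr)$coefficients
  W[is.na(W)] <- 0
  scores <- cbind(1, rates[is_test, , drop = FALSE]) %*% W
  pred <- classes[max.col(scores, ties.method = "first")]
  list(predicted = pred, truth = labels[is_test],
       accuracy = mean(pred == labels[is_test]), W = W)
}

#' @rdname phase_decoder
#' @param n_folds cross-validation folds (trials are partitioned into
#'   folds; each fold is decoded by a model trained on the others).
#' @return `phase_decoding_accuracy`: the overall held-out accuracy.
#' @export
phase_decoding_accuracy <- function(rates, labels, trial, n_folds = 5L) {
  ids <- unique(trial)
  folds <- split(sample(ids), rep_len(seq_len(n_folds), length(ids)))
  hits <- n <- 0
  for (f in folds) {
    d <- phase_decoder(rates, labels, trial, test_trials = f)
    hits <- hits + sum(d$predicted == d$truth)
    n <- n + length(d$truth)
  }
  hits / n
}

#' Pairwise rate correlations per phase and their preservation
#'
#' Pearson correlation between every neuron pair's (filtered) rates,
#' computed separately per task phase; structure preservation across two
#' phases is the Pearson correlation between the off-diagonal entries of
#' their matrices (the correlation of correlations). Neurons silent
#' (zero-variance) in any requested phase are excluded and counted.
#'
#' @param rates `N x n_neurons` filtered rate matrix.
#' @param labels phase label per sample (LM1a/b merged into LM1).
#' @param phases the phases to compute matrices for.
#' @return list with `matrices` (named list), `corr_of_corr` (data.frame of
#'   all phase pairs), `n_excluded`.
#' @export
pairwise_correlations <- function(rates, labels,
                                  phases = c("LM0", "LM1", "LM2")) {
  labels <- sub("^LM1[ab]$", "LM1", labels)
  phases <- intersect(phases, unique(labels))
  ok <- rep(TRUE, ncol(rates))
  for (ph in phases) {
    ok <- ok & apply(rates[labels == ph, , drop = FALSE], 2, sd) > 0
  }
  mats <- lapply(phases, function(ph)
    cor(rates[labels == ph, ok, drop = FALSE]))
  names(mats) <- phases
  prs <- if (length(phases) >= 2) t(combn(phases, 2)) else
    matrix(character(0), 0, 2)
  cc <- data.frame(phase_a = prs[, 1], phase_b = prs[, 2],
                   corr_of_corr = apply(prs, 1, function(pr) {
                     off <- upper.tri(mats[[pr[1]]])
                     cor(mats[[pr[1]]][off], mats[[pr[2]]][off])
                   }))
  list(matrices = mats, corr_of_corr = cc, n_excluded = sum(!ok))
}

#' Cross-population prediction of a neuron's rate
#'
#' Predicts one neuron's band-passed, subsampled rate from the other
#' neurons' rates at lags 0..`lags - 1` with L1-regularized (lasso) linear
#' regression, fitting within one condition and evaluating (with frozen
#' coefficients) within the same or another condition. Goodness of fit is
#' `R^2 = 1 - sum((Y - Y_pred)^2) / sum((Y - mean(Y))^2)` on the
#' evaluation samples.
#'
#' @param rate_trace a `rate_trace` from [bandpass_rates()].
#' @param labels condition label per retained sample (same timebase).
#' @param target_neuron column index of the predicted neuron.
#' @param phase_train,phase_test condition labels for fitting and
#'   evaluation.
#' @param lags number of lags (default 8, about 2.5 s at 3.3 Hz).
#' @param lambda lasso penalty.
#' @return list with `r2`, `r2_within` (fit condition, fitted samples),
#'   `n_coef` (nonzero coefficients); `r2` is `NA` (flagged degenerate)
#'   when the target is constant in the evaluation condition.
#' @export
rate_prediction_r2 <- function(rate_trace, labels, target_neuron,
                               phase_train, phase_test = phase_train,
                               lags = 8L, lambda = 1e-4) {
  R <- rate_trace$rates
  labels <- sub("^LM1[ab]$", "LM1", labels)
  stopifnot(nrow(R) == length(labels))
  others <- setdiff(seq_len(ncol(R)), target_neuron)
  N <- nrow(R)
  lag_block <- function(l) rbind(matrix(0, l, length(others)),
                                 R[seq_len(N - l), others, drop = FALSE])
  X <- do.call(cbind, lapply(0:(lags - 1L), lag_block))
  Y <- R[, target_neuron]
  rows_tr <- which(labels == phase_train)[-seq_len(lags)]
  rows_te <- which(labels == phase_test)[-seq_len(lags)]
  fit <- glmnet::glmnet(X[rows_tr, ], Y[rows_tr], alpha = 1,
                        lambda = lambda, standardize = TRUE)
  r2_of <- function(rows) {
    yp <- as.numeric(predict(fit, X[rows, ]))
    yt <- Y[rows]
    ss <- sum((yt - mean(yt))^2)
    if (ss == 0) return(NA_real_)
    1 - sum((yt - yp)^2) / ss
  }
  list(r2 = r2_of(rows_te), r2_within = r2_of(rows_tr),
       n_coef = sum(coef(fit)[-1] != 0))
}

#' Within- versus across-group distances of population states
#'
#' Compares mean pairwise Euclidean distances between state vectors within
#' two groups against distances across the groups, with percentile
#' bootstrap CIs (resampling trials within groups). Separated CIs for
#' across > within indicate group (context) encoding.
#'
#' @param states `n_trials x d` state matrix (raw rates or a low-D
#'   embedding), one row per trial.
#' @param groups group label per row (two levels).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @return list with `within`, `across` (means), `ci_within`, `ci_across`,
#'   and `separated` (`TRUE` when the across CI lies entirely above the
#'   within CI).
#' @export
group_distance_test <- function(states, groups, n_boot = 1000L,
                                conf = 0.95) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  if (min(table(groups)) < 2) stop("each group needs at least 2 trials")
  D <- as.matrix(dist(states))
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  mean_within <- function(i1, i2) {
    w <- c(D[i1, i1][upper.tri(diag(length(i1)))],
           D[i2, i2][upper.tri(diag(length(i2)))])
    mean(w)
  }
  mean_across <- function(i1, i2) mean(D[i1, i2])
  bs <- t(vapply(seq_len(n_boot), function(k) {
    i1 <- sample(g1, replace = TRUE)
    i2 <- sample(g2, replace = TRUE)
    c(mean_within(i1, i2), mean_across(i1, i2))
  }, c(0, 0)))
  al <- (1 - conf) / 2
  ci_w <- quantile(bs[, 1], c(al, 1 - al), names = FALSE, na.rm = TRUE)
  ci_a <- quantile(bs[, 2], c(al, 1 - al), names = FALSE, na.rm = TRUE)
  list(within = mean_within(g1, g2), across = mean_across(g1, g2),
       ci_within = ci_w, ci_across = ci_a,
       separated = ci_a[1] > ci_w[2])
}

#' Stability of pairwise trial distances across sliding spike-count windows
#'
#' Tests whether neural trajectories evolve smoothly (nearby trials remain
#' nearby): raw spike counts (no smoothing) in a baseline window covering
#' the last `window` seconds before the second landmark encounter give a
#' set of pairwise trial distances, which are correlated with the pairwise
#' distances in a sliding window at increasing offsets. Offset 0 is the
#' first position where the windows no longer overlap. A per-session
#' shuffle control (permuting neuron identity independently per trial)
#' gives the chance level; bootstrap CIs resample trials.
#'
#' @param session a `spike_session`.
#' @param trials trial ids to use (e.g. a matched subset); all by default.
#' @param window window length (s).
#' @param max_offset largest window offset (s).
#' @param step offset increment (s).
#' @param n_shuffle shuffles for the chance level.
#' @param n_boot bootstrap resamples for the CIs.
#' @return data.frame with `offset`, `R`, `ci_lo`, `ci_hi`, and attribute
#'   `"shuffle_level"` (the 95% shuffle quantile of R).
#' @export
window_distance_correlation <- function(session, trials = NULL,
                                        window = 0.75, max_offset = 2,
                                        step = 0.25, n_shuffle = 100L,
                                        n_boot = 1000L) {
  if (is.null(trials)) trials <- session$trial_info$trial
  if (length(trials) < 3) stop("need at least 3 trials for pairwise distances")
  fs <- session$cfg$sample_rate
  nw <- round(window * fs)
  info <- session$trial_info
  counts_in <- function(tr, from) {  # 'from' in samples rel. to trial start
    i0 <- which(session$trial == tr)[1]
    idx <- (i0 + from):(i0 + from + nw - 1L)
    idx <- idx[idx >= i0 & idx <= i0 + sum(session$trial == tr) - 1L]
    colSums(session$counts[idx, , drop = FALSE])
  }
  enc2 <- round(info$t_enc2[match(trials, info$trial)] * fs)
  base <- t(vapply(seq_along(trials), function(k)
    counts_in(trials[k], enc2[k] - nw), numeric(session$n_neurons)))
  d_base <- dist(base)
  offsets <- seq(-window, max_offset, by = step)
  pair_idx <- which(upper.tri(matrix(0, length(trials), length(trials))),
                    arr.ind = TRUE)
  res <- lapply(offsets, function(o) {
    cur <- t(vapply(seq_along(trials), function(k)
      counts_in(trials[k], enc2[k] + round(o * fs)),
      numeric(session$n_neurons)))
    d_cur_m <- as.matrix(dist(cur))
    d_base_m <- as.matrix(d_base)
    R <- cor(d_base_m[pair_idx], d_cur_m[pair_idx])
    bs <- vapply(seq_len(n_boot), function(i) {
      tr_i <- sample(seq_along(trials), replace = TRUE)
      sub <- which(upper.tri(diag(length(tr_i))), arr.ind = TRUE)
      a <- d_base_m[cbind(tr_i[sub[, 1]], tr_i[sub[, 2]])]
      b <- d_cur_m[cbind(tr_i[sub[, 1]], tr_i[sub[, 2]])]
      if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
    }, 0)
    sh <- vapply(seq_len(n_shuffle), function(i) {
      shuf <- t(apply(cur, 1, sample))
      cor(d_base_m[pair_idx], as.matrix(dist(shuf))[pair_idx])
    }, 0)
    c(R = R, lo = quantile(bs, 0.025, names = FALSE, na.rm = TRUE),
      hi = quantile(bs, 0.975, names = FALSE, na.rm = TRUE),
      sh = quantile(sh, 0.95, names = FALSE))
  })
  res <- do.call(rbind, res)
  out <- data.frame(offset = offsets, R = res[, "R"],
                    ci_lo = res[, "lo"], ci_hi = res[, "hi"])
  attr(out, "shuffle_level") <- max(res[, "sh"])
  out
}

#' Tuning entropy in the global versus landmark-relative frame
#'
#' Firing-rate tuning curves over `[-pi, pi)` in 6 bins, computed either on
#' the global arena angle or on the angle relative to the last seen
#' landmark, summarized per neuron by [entropy_rel_uniform()]. Only
#' samples with radial eccentricity above `ecc_frac` of the arena radius
#' enter; LM1 and LM2 sample counts are matched by random subsampling; LM0
#' samples are excluded in the relative frame (no landmark seen yet).
#'
#' @param session a `spike_session`.
#' @param rates rate matrix aligned to session samples (ground-truth rates
#'   by default).
#' @param frame `"global"` or `"relative"`.
#' @param n_bins tuning bins.
#' @param ecc_frac eccentricity gate as a fraction of the arena radius.
#' @return data.frame with `neuron`, `phase` (LM1/LM2), `entropy` (bits).
#' @export
frame_tuning_entropy <- function(session, rates = session$rates,
                                 frame = c("global", "relative"),
                                 n_bins = 6L, ecc_frac = 0.7) {
  frame <- match.arg(frame)
  phase <- sub("^LM1[ab]$", "LM1", session$phase)
  sel <- session$radius > ecc_frac * session$cfg$arena_radius &
    phase %in% c("LM1", "LM2")
  if (frame == "relative") sel <- sel & !is.na(session$last_lm_angle)
  i1 <- which(sel & phase == "LM1")
  i2 <- which(sel & phase == "LM2")
  n <- min(length(i1), length(i2))
  if (n < n_bins) stop("too few gated samples to form tuning curves")
  i1 <- sample(i1, n); i2 <- sample(i2, n)
  ang <- if (frame == "global") circ_diff(session$angle, 0) else
    circ_diff(session$angle, session$last_lm_angle)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  ent_of <- function(idx) {
    b <- findInterval(ang[idx], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    vapply(seq_len(ncol(rates)), function(u) {
      cu <- vapply(seq_len(n_bins), function(k) {
        r <- idx[b == k]
        if (length(r) == 0) NA_real_ else mean(rates[r, u])
      }, 0)
      entropy_rel_uniform(cu[!is.na(cu)])
    }, 0)
  }
  rbind(data.frame(neuron = seq_len(ncol(rates)), phase = "LM1",
                   entropy = ent_of(i1)),
        data.frame(neuron = seq_len(ncol(rates)), phase = "LM2",
                   entropy = ent_of(i2)))
}

#' Normalized eigenvalue spectrum of the rate covariance
#'
#' Eigenvalues of the covariance of (filtered) rates, normalized to sum 1
#' (fraction of explained variance per component), with a control spectrum
#' from time-shuffled data (independent random circular shifts per neuron,
#' which preserve each autocorrelation but destroy shared structure).
#' Significant components are the leading eigenvalues exceeding the
#' per-rank 95% shuffle quantile.
#'
#' @param rates `N x n_neurons` rate matrix.
#' @param n_shuffle shuffle repetitions.
#' @return list with `spectrum`, `control` (per-rank 95% quantiles),
#'   `n_significant`.
#' @export
pca_spectrum <- function(rates, n_shuffle = 20L) {
  stopifnot(ncol(rates) >= 2)
  ev <- function(M) {
    e <- eigen(cov(M), symmetric = TRUE, only.values = TRUE)$values
    e <- pmax(e, 0)
    e / sum(e)
  }
  spec <- ev(rates)
  N <- nrow(rates)
  ctrl <- vapply(seq_len(n_shuffle), function(i) {
    sh <- apply(rates, 2, function(col) {
      k <- sample.int(N, 1)
      col[((seq_len(N) + k - 1L) %% N) + 1L]
    })
    ev(sh)
  }, numeric(length(spec)))
  ctrl95 <- apply(ctrl, 1, quantile, probs = 0.95, names = FALSE)
  above <- spec > ctrl95
  n_sig <- if (all(above)) length(above) else which(!above)[1] - 1L
  list(spectrum = spec, control = ctrl95, n_significant = n_sig)
}
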