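#' Position tuning curves of a population
#'
#' Mean activation of each unit per position bin, with per-unit preferred
#' location (bin centre of the curve maximum; flat ties resolve to the
#' lowest bin index). Bins with no samples are returned as `NA` and flagged.
#'
#' @param acts `N x n_units` activation (or rate) matrix, one row per
#'   timestep sample.
#' @param positions angular positions (rad), length `N`.
#' @param n_bins number of position bins (50 for the preferred-location
#'   analysis, 20 for the phase-conditioned tuning analyses).
#' @param select optional logical/integer row filter (e.g. post-second-
#'   encounter steps of one phase).
#' @return a `tuning_curve_set`: list with `curves` (`n_units x n_bins`),
#'   `bin_centers`, `preferred` (rad per unit), `empty_bins` (logical).
#' @export
tuning_curves <- function(acts, positions, n_bins = 50L, select = NULL) {
  if (!is.null(select)) {
    acts <- acts[select, , drop = FALSE]
    positions <- positions[select]
  }
  stopifnot(nrow(acts) == length(positions), nrow(acts) > 0)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  bin <- findInterval(wrap_angle(positions), edges,
                      rightmost.closed = TRUE, all.inside = TRUE)
  curves <- matrix(NA_real_, ncol(acts), n_bins)
  for (k in seq_len(n_bins)) {
    rows <- bin == k
    if (any(rows)) curves[, k] <- colMeans(acts[rows, , drop = FALSE])
  }
  empty <- colSums(!is.na(curves)) == 0
  pref <- apply(curves, 1, function(cu) {
    cu[is.na(cu)] <- -Inf  # empty bins cannot carry the maximum
    centers[which.max(cu)]
  })
  structure(list(curves = curves, bin_centers = centers, preferred = pref,
                 empty_bins = empty, n_bins = n_bins),
            class = "tuning_curve_set")
}

#' Density ratio of preferred locations near landmarks
#'
#' Compares the density (count per unit angle) of unit preferred locations
#' within `d_enc` of any landmark against the density elsewhere on the
#' circle. A ratio above 1 means the population over-represents landmark
#' locations.
#'
#' @param tuning a `tuning_curve_set`.
#' @param env an `environment_map`.
#' @param d_enc angular threshold defining "near a landmark" (rad).
#' @return list with `ratio` (`Inf` flag when no unit prefers a location
#'   away from landmarks), `n_near`, `n_far`, and the angular fractions of
#'   the circle covered by each zone.
#' @export
preferred_location_density <- function(tuning, env, d_enc = pi / 20) {
  pref <- tuning$preferred
  dmin <- apply(vapply(env$landmarks, function(l) circ_dist(pref, l),
                       numeric(length(pref))), 1, min)
  near <- dmin <= d_enc
  # zones around landmarks never overlap (separation >= delta_sep > 2 d_enc)
  arc_near <- length(env$landmarks) * 2 * d_enc
  arc_far <- 2 * pi - arc_near
  dens_near <- sum(near) / arc_near
  dens_far <- sum(!near) / arc_far
  list(ratio = if (dens_far > 0) dens_near / dens_far else Inf,
       n_near = sum(near), n_far = sum(!near),
       frac_near = arc_near / (2 * pi), frac_far = arc_far / (2 * pi))
}

#' Project test states onto training-state principal directions
#'
#' Fits PCA on hidden states from training-distribution trials and projects
#' (mean-centred with the training mean) states from a test configuration
#' onto the top `k` principal directions.
#'
#' @param H_train `N x d` training-state matrix.
#' @param H_test `M x d` test-state matrix (defaults to the training states).
#' @param k number of components.
#' @return list with `scores` (`M x k`), `rotation`, `center`,
#'   `var_explained` (fraction per component).
#' @export
state_pca <- function(H_train, H_test = H_train, k = 3L) {
  pc <- prcomp(H_train, center = TRUE, scale. = FALSE)
  k_eff <- min(k, ncol(pc$rotation))
  if (k_eff < k) warning("rank-deficient states: returning ", k_eff,
                         " components")
  rot <- pc$rotation[, seq_len(k_eff), drop = FALSE]
  scores <- sweep(H_test, 2, pc$center) %*% rot
  list(scores = scores, rotation = rot, center = pc$center,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k_eff)])
}

#' Correlation dimension of a point cloud
#'
#' Grassberger-Procaccia-style estimate of the local (fractal) dimension of
#' a state cloud: the number of neighbors within a ball of radius `r` grows
#' as `r^d` when the data are locally `d`-dimensional. The cloud is first
#' reduced to `n_components` principal components; from `n_base` randomly
#' chosen base points, neighbors are counted (excluding the base point) at
#' log-spaced radii. The minimum radius is set so that the log of the mean
#' neighbor count is near 1, the maximum is 10 times the minimum, and the
#' dimension is the slope of the linear part of log mean-count versus log
#' radius. "Linear part" is operationalized as the flattest segment of the
#' count curve: the four consecutive local slopes with the smallest
#' relative spread seed the window, which then extends in both directions
#' while local slopes stay within `slope_tol` of the window median. This
#' picks the power-law plateau between the two regimes that bend the
#' curve: measurement-noise inflation at small radii and boundary/density
#' falloff at large radii. The fitted window is reported.
#'
#' @param states `N x d` state matrix.
#' @param n_components principal components retained before counting.
#' @param n_base number of base points.
#' @param n_radii radii per decade-spanning grid.
#' @param slope_tol relative deviation from the reference slope allowed
#'   inside the fitted window.
#' @param time_index optional per-point time stamps (any monotone unit;
#'   points from different trials should differ by more than `theiler`).
#' @param theiler Theiler exclusion window: neighbors closer than this in
#'   `time_index` are not counted, so that temporally adjacent samples
#'   along a smooth trajectory do not masquerade as a one-dimensional
#'   manifold. 0 disables the exclusion.
#' @return list with `dimension`, `radii`, `mean_counts`, `window`
#'   (logical, radii used in the fit) and `r_min`.
#' @export
correlation_dimension <- function(states, n_components = 20L, n_base = 1000L,
                                  n_radii = 20L, slope_tol = 0.1,
                                  time_index = NULL, theiler = 0) {
  states <- as.matrix(states)
  if (nrow(states) < max(50, n_base / 10))
    stop("too few points for neighbor statistics")
  d_keep <- min(n_components, ncol(states))
  if (ncol(states) > d_keep) {
    pc <- prcomp(states, center = TRUE, scale. = FALSE)
    states <- pc$x[, seq_len(d_keep), drop = FALSE]
  }
  n_base <- min(n_base, nrow(states))
  base_idx <- sample.int(nrow(states), n_base)
  tind <- if (is.null(time_index)) numeric(0) else as.numeric(time_index)
  ncount <- function(r) cpp_neighbor_counts(states, base_idx - 1L, r,
                                            tind, theiler)
  # coarse scan to locate r_min: log mean neighbor count ~ 1
  span <- sqrt(sum(apply(states, 2, function(x) diff(range(x))^2)))
  scan_r <- exp(seq(log(span * 1e-4), log(span), length.out = 40))
  scan_c <- colMeans(ncount(scan_r))
  lmc <- log(pmax(scan_c, 1e-12))
  if (max(lmc) < 1) stop("too few points for neighbor statistics")
  i0 <- which(lmc >= 1)[1]
  r_min <- if (i0 == 1) scan_r[1] else {
    # log-log interpolate to log mean count = 1
    exp(log(scan_r[i0 - 1]) + (1 - lmc[i0 - 1]) / (lmc[i0] - lmc[i0 - 1]) *
          (log(scan_r[i0]) - log(scan_r[i0 - 1])))
  }
  radii <- exp(seq(log(r_min), log(10 * r_min), length.out = n_radii))
  counts <- colMeans(ncount(radii))
  keep <- counts > 0
  lr <- log(radii[keep]); lc <- log(counts[keep])
  sl <- diff(lc) / diff(lr)                  # local slopes between radii
  L <- min(4L, length(sl))
  spread <- vapply(seq_len(length(sl) - L + 1), function(i) {
    w <- sl[i:(i + L - 1)]
    (max(w) - min(w)) / max(abs(median(w)), 1e-12)
  }, 0)
  i0 <- which.min(spread)
  lo <- i0; hi <- i0 + L - 1L
  repeat {
    md <- median(sl[lo:hi])
    grew <- FALSE
    if (lo > 1 && abs(sl[lo - 1] - md) <= slope_tol * abs(md)) {
      lo <- lo - 1L; grew <- TRUE
    }
    if (hi < length(sl) && abs(sl[hi + 1] - md) <= slope_tol * abs(md)) {
      hi <- hi + 1L; grew <- TRUE
    }
    if (!grew) break
  }
  win <- lo:(hi + 1L)                        # slope i covers radii i, i+1
  fit <- lm.fit(cbind(1, lr[win]), lc[win])
  window <- logical(length(radii))
  window[which(keep)[win]] <- TRUE
  list(dimension = unname(fit$coefficients[2]), radii = radii,
       mean_counts = counts, window = window, r_min = r_min)
}

#' Find activity bumps on the circle
#'
#' Local maxima above a threshold in a circular activity profile (an output
#' population or a particle density). Neighboring candidates closer than
#' `min_sep` bins collapse onto the larger one, so a jagged peak counts
#' once.
#'
#' @param v activations around the circle (one value per equally spaced
#'   angle).
#' @param threshold minimum height of a bump.
#' @param min_sep minimum separation between distinct bumps, in bins.
#' @return integer vector of bump indices into `v` (possibly empty).
#' @export
find_bumps <- function(v, threshold = 0.1, min_sep = 3L) {
  n <- length(v)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  cand <- which(v > threshold & v >= v[nxt] & v >= v[prv])
  if (length(cand) <= 1) return(cand)
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == 0 ||
        min(pmin(abs(i - kept), n - abs(i - kept))) >= min_sep)
      kept <- c(kept, i)
  }
  sort(kept)
}

#' Timing and accuracy of location disambiguation
#'
#' For a two-landmark trial, constructs the trajectory of the alternative
#' location hypothesis (the true trajectory shifted by the signed
#' inter-landmark distance: the estimate of an agent that mistook the first
#' encountered landmark for the other one), tracks the output units nearest
#' the true and alternative trajectories, and reports:
#' * `t_disambig`: the earliest step after which one of the two bump
#'   heights stays below `threshold` through trial end (`NA` if neither
#'   collapses);
#' * `correct`: whether the decoded estimate at the last encounter is
#'   circularly closer to the true than to the wrong landmark.
#'
#' @param O `T x n_out` output activations.
#' @param traj the true `trajectory`.
#' @param env a two-landmark `environment_map`.
#' @param encounters an `encounter_log` with at least 2 events.
#' @param threshold bump-collapse threshold.
#' @param cfg a [sim_config()].
#' @return a `disambiguation_result`: list with `t_disambig`, `correct`,
#'   `bump_true`, `bump_alt` (per-step activations).
#' @export
disambiguation_metrics <- function(O, traj, env, encounters, threshold = 0.1,
                                   cfg = sim_config()) {
  stopifnot(length(env$landmarks) == 2, nrow(encounters) >= 2)
  z <- place_cell_grid(ncol(O))
  first_lm <- encounters$landmark[1]
  other_lm <- ifelse(first_lm == 1L, 2L, 1L)
  shift <- circ_diff(env$landmarks[other_lm], env$landmarks[first_lm])
  y_alt <- wrap_angle(traj$y + shift)
  T <- nrow(O)
  idx_true <- vapply(traj$y, function(a) which.min(circ_dist(a, z)), 1L)
  idx_alt <- vapply(y_alt, function(a) which.min(circ_dist(a, z)), 1L)
  bump_true <- O[cbind(seq_len(T), idx_true)]
  bump_alt <- O[cbind(seq_len(T), idx_alt)]
  below_to_end <- function(bv) {
    ok <- rev(cumprod(rev(bv < threshold))) == 1
    if (any(ok)) which(ok)[1] else NA_integer_
  }
  t_d <- suppressWarnings(min(below_to_end(bump_true), below_to_end(bump_alt),
                              na.rm = TRUE))
  if (!is.finite(t_d)) t_d <- NA_integer_
  t_last <- encounters$t[nrow(encounters)]
  est_last <- decode_location(O, cfg)$y_hat[t_last]
  lm_true <- env$landmarks[encounters$landmark[nrow(encounters)]]
  lm_wrong <- env$landmarks[ifelse(encounters$landmark[nrow(encounters)] == 1L,
                                   2L, 1L)]
  structure(list(t_disambig = t_d,
                 correct = circ_dist(est_last, lm_true) <
                   circ_dist(est_last, lm_wrong),
                 bump_true = bump_true, bump_alt = bump_alt),
            class = "disambiguation_result")
}

#' Preservation of pairwise tuning-correlation structure across phases
#'
#' Computes the Pearson correlation between every pair of unit tuning
#' curves within each of two task phases, then summarizes structure
#' preservation as the Pearson correlation between the off-diagonal entries
#' of the two matrices. Units with constant (or undefined) curves in either
#' phase are excluded and counted.
#'
#' @param curves_a,curves_b `tuning_curve_set`s for the two phases (same
#'   units, same bins).
#' @return list with `corr_a`, `corr_b` (unit-pair correlation matrices),
#'   `corr_of_corr` (the summary; symmetric in its arguments),
#'   `n_excluded` (units dropped).
#' @export
tuning_correlation_structure <- function(curves_a, curves_b) {
  A <- curves_a$curves; B <- curves_b$curves
  stopifnot(nrow(A) == nrow(B))
  ok_bins <- colSums(is.na(A)) == 0 & colSums(is.na(B)) == 0
  A <- A[, ok_bins, drop = FALSE]; B <- B[, ok_bins, drop = FALSE]
  usable <- apply(A, 1, sd) > 0 & apply(B, 1, sd) > 0
  A <- A[usable, , drop = FALSE]; B <- B[usable, , drop = FALSE]
  Ca <- cor(t(A)); Cb <- cor(t(B))
  off <- upper.tri(Ca)
  list(corr_a = Ca, corr_b = Cb,
       corr_of_corr = cor(Ca[off], Cb[off]),
       n_excluded = sum(!usable))
}

#' Phase-conditioned rate histograms over position
#'
#' The trial-to-trial variability display: for each unit, a 2D histogram of
#' activation (rows) against binned position (columns), per task phase.
#' Columns are normalized to equal sum, so a unit that takes one of two
#' phase-dependent rates at a location shows up as a bimodal column. The
#' first step of each trial and steps with nonzero landmark input are
#' excluded before binning.
#'
#' @param acts `N x n_units` stacked activations.
#' @param positions stacked positions (rad, or displacement in a chosen
#'   frame mapped to `[0, 2*pi)`).
#' @param phases character vector of phase labels per sample.
#' @param exclude logical vector of samples to drop (first trial steps,
#'   landmark-input steps).
#' @param n_pos_bins,n_rate_bins histogram resolution (100 x 10).
#' @return nested list `result[[phase]][[unit]]`: `n_rate_bins x n_pos_bins`
#'   column-normalized histograms (empty columns are all-`NA` and flagged
#'   via the `"empty_cols"` attribute).
#' @export
conditional_rate_histograms <- function(acts, positions, phases,
                                        exclude = NULL, n_pos_bins = 100L,
                                        n_rate_bins = 10L) {
  if (!is.null(exclude)) {
    acts <- acts[!exclude, , drop = FALSE]
    positions <- positions[!exclude]
    phases <- phases[!exclude]
  }
  pos_edges <- seq(0, 2 * pi, length.out = n_pos_bins + 1)
  out <- list()
  for (ph in unique(phases)) {
    rows <- phases == ph
    A <- acts[rows, , drop = FALSE]
    pb <- findInterval(wrap_angle(positions[rows]), pos_edges,
                       rightmost.closed = TRUE, all.inside = TRUE)
    per_unit <- lapply(seq_len(ncol(A)), function(u) {
      rng <- range(A[, u])
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      re <- seq(rng[1], rng[2], length.out = n_rate_bins + 1)
      rb <- findInterval(A[, u], re, rightmost.closed = TRUE,
                         all.inside = TRUE)
      Hc <- matrix(0, n_rate_bins, n_pos_bins)
      tab <- table(factor(rb, levels = 1:n_rate_bins),
                   factor(pb, levels = 1:n_pos_bins))
      Hc[] <- as.numeric(tab)
      cs <- colSums(Hc)
      empty <- cs == 0
      Hc <- sweep(Hc, 2, pmax(cs, 1), "/")
      Hc[, empty] <- NA_real_
      attr(Hc, "empty_cols") <- empty
      Hc
    })
    out[[ph]] <- per_unit
  }
  out
}
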