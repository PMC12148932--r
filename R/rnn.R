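#' Initialize a recurrent localization network
#'
#' Three layers of rate neurons: an input layer (80 cells in the
#' external-map scheme, 11 in the internal-map scheme) projecting into 128
#' recurrently connected tanh units, projecting into 70 tanh output units.
#' All weights are trained. The hidden state starts at zero at each trial.
#'
#' Initialization (the training target selection by validation loss absorbs
#' most of its influence): input and output weights uniform in
#' `±1/sqrt(fan_in)`, recurrent weights a random orthogonal matrix, biases
#' zero. The per-cell velocity input code is drawn here and stored with the
#' model so inputs and network stay consistent.
#'
#' @param cfg a [sim_config()]; its `scheme` selects the input width.
#' @param nonneg use the non-negative variant, which rectifies the hidden
#'   preactivation before the tanh.
#' @param velocity_code optional velocity input code; drawn if `NULL`.
#' @param n_hidden hidden layer width.
#' @return a `ringnav_net`: list with `Wx` (`n_hidden x n_in`), `Wh`, `b`,
#'   `Wo` (`n_out x n_hidden`), `bo`, `nonneg`, `scheme`, `velocity_code`,
#'   `cfg`.
#' @export
init_network <- function(cfg = sim_config(), nonneg = FALSE,
                         velocity_code = NULL, n_hidden = 128L) {
  n_in <- n_input_cells(cfg)
  n_h <- as.integer(n_hidden)
  if (is.null(velocity_code)) velocity_code <- sample_velocity_code(cfg)
  ru <- function(nr, nc) matrix(runif(nr * nc, -1, 1) / sqrt(nc), nr, nc)
  Wh <- qr.Q(qr(matrix(rnorm(n_h * n_h), n_h, n_h)))
  # start the output at the marginal mean of the place-cell targets, so
  # early training refines structure instead of fitting the mean
  m_tar <- mean(vm_bump(seq(0, 2 * pi, length.out = 1024), cfg$sigma_o))
  structure(list(
    Wx = ru(n_h, n_in), Wh = Wh, b = numeric(n_h),
    Wo = ru(cfg$n_out, n_h), bo = rep(atanh(m_tar), cfg$n_out),
    nonneg = nonneg, scheme = cfg$scheme,
    velocity_code = velocity_code, cfg = cfg
  ), class = "ringnav_net")
}

#' @export
print.ringnav_net <- function(x, ...) {
  cat(sprintf("ringnav_net: %s%s, %d -> %d -> %d units\n", x$scheme,
              if (x$nonneg) " (non-negative)" else "",
              ncol(x$Wx), nrow(x$Wh), nrow(x$Wo)))
  vl <- attr(x, "val_loss")
  if (!is.null(vl)) cat(sprintf("  best validation loss: %.5g\n", vl))
  invisible(x)
}

#' Run the network forward
#'
#' Computes hidden and output activations for one trial (a `T x n_in` input
#' matrix or a `trial`) from a zero initial hidden state:
#' `h_t = tanh(Wx x_t + Wh h_{t-1} + b)` (preactivation rectified first in
#' the non-negative variant) and `o_t = tanh(Wo h_t + bo)`.
#'
#' @param net a `ringnav_net`.
#' @param x a `trial`, or a `T x n_in` input matrix.
#' @return list with `H` (`T x n_hidden`) and `O` (`T x n_out`).
#' @export
rnn_forward <- function(net, x) {
  X <- if (inherits(x, "trial")) x$X else x
  stopifnot(is.matrix(X), ncol(X) == ncol(net$Wx))
  cube <- array(t(X), dim = c(ncol(X), 1L, nrow(X)))
  out <- cpp_rnn_forward(net$Wx, net$Wh, net$b, net$Wo, net$bo, cube,
                         net$nonneg)
  list(H = t(out$H[, 1, , drop = TRUE]), O = t(out$O[, 1, , drop = TRUE]))
}

# forward for a list of trials via batched slices; returns per-trial lists
rnn_forward_trials <- function(net, trials, batch = 64L) {
  n <- length(trials)
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batch - 1L, n)
    Xc <- trial_cube(trials[idx], ncol(net$Wx))$X
    fw <- cpp_rnn_forward(net$Wx, net$Wh, net$b, net$Wo, net$bo, Xc,
                          net$nonneg)
    for (k in seq_along(idx)) {
      out[[idx[k]]] <- list(H = t(fw$H[, k, , drop = TRUE]),
                            O = t(fw$O[, k, , drop = TRUE]))
    }
    i <- i + batch
  }
  out
}

# fast training-batch generator: builds one batch of config-1 trials as
# input/target cubes directly, vectorizing trajectories, velocity coding
# and targets across the batch; landmark-window content and encounter
# semantics are shared with the per-trial path (encounter_core, vm_bump)
training_cube <- function(B, cfg, velocity_code) {
  T <- cfg$n_steps
  n_in <- n_input_cells(cfg)
  tb <- trajectory_batch(cfg, B)
  disp <- tb$v * cfg$dt + matrix(rnorm(T * B, 0, cfg$sigma_v), T, B)
  v_rep <- pmin(pmax(disp / cfg$dt, -cfg$v_max), cfg$v_max)
  ut <- t((v_rep + cfg$v_max) / (2 * cfg$v_max))   # B x T
  X <- array(0, dim = c(n_in, B, T))
  for (j in seq_len(cfg$n_vel)) {
    X[j, , ] <- velocity_code$min[j] +
      ut * (velocity_code$max[j] - velocity_code$min[j])
  }
  z <- place_cell_grid(cfg$n_out)
  O <- cpp_target_cube(tb$y, z, cfg$sigma_o)
  internal <- cfg$scheme == "internal_map"
  for (b in seq_len(B)) {
    lms <- if (internal) {
      fixed_environment(sample(c("e1", "e2", "e3", "e4"), 1))$landmarks
    } else {
      sample_environment(sample(2:4, 1), cfg)$landmarks
    }
    ev <- encounter_core(tb$y[, b], lms, cfg$d_enc)
    for (e in seq_along(ev$t)) {
      w <- ev$t[e]:min(ev$t[e] + 3L, T)
      if (internal) {
        X[n_in, b, w] <- 1
      } else {
        lt <- wrap_angle(lms + rnorm(1, 0, cfg$sigma_l))
        X[(cfg$n_vel + 1):n_in, b, w] <-
          colSums(vm_bump(outer(lt, z, "-"), cfg$sigma_w))
      }
    }
  }
  list(X = X, O = O)
}

# stack trials into (cells, batch, time) cubes for the C++ kernels
trial_cube <- function(trials, n_in) {
  B <- length(trials)
  T <- nrow(trials[[1]]$X)
  n_out <- ncol(trials[[1]]$target)
  X <- array(0, dim = c(n_in, B, T))
  O <- array(0, dim = c(n_out, B, T))
  for (b in seq_len(B)) {
    X[, b, ] <- t(trials[[b]]$X)
    O[, b, ] <- t(trials[[b]]$target)
  }
  list(X = X, O = O)
}

#' Train the network
#'
#' Stochastic gradient descent with Adam on the mean squared error between
#' outputs and place-cell targets, averaged over neurons, time within each
#' trial, and trials. Gradients are clipped to global norm `grad_clip`.
#' Training trials are generated independently on the fly from the training
#' distribution (configuration 1 under the network's scheme). Performance
#' is monitored on a fixed validation set of `n_val` independent trials and
#' the parameters with the smallest validation error are returned.
#'
#' The full-scale reference setting is 1e6 independently generated trials
#' (one pass). The desk-scale preset keeps the same optimizer but makes
#' the update budget affordable on one CPU by cycling several epochs over
#' a smaller pool of independently generated trials (`epochs > 1`), with
#' overfitting controlled by the validation-based selection.
#'
#' @param net a `ringnav_net` from [init_network()].
#' @param n_trials number of independently generated training trials.
#' @param batch_size trials per gradient step.
#' @param lr Adam learning rate (Adam defaults `beta1 = 0.9`,
#'   `beta2 = 0.999`, `eps = 1e-8`). A vector gives a piecewise-constant
#'   decay schedule over the phases defined by `lr_breaks`.
#' @param lr_breaks fractions of the update budget at which the next
#'   learning rate in `lr` takes over; length `length(lr) - 1`. `NULL`
#'   splits the budget into equal phases.
#' @param grad_clip global gradient-norm clip.
#' @param n_val validation set size.
#' @param val_every validate (and checkpoint the best parameters) every this
#'   many batches.
#' @param epochs passes over the training trials. 1 streams freshly
#'   generated batches and never stores them; larger values materialize a
#'   pool of `n_trials` trials and revisit it in random order, drawing a
#'   fresh pool at each learning-rate phase.
#' @param generator optional function `(n)` returning a list of `n` trials;
#'   defaults to the training distribution.
#' @param precision arithmetic of the gradient kernel: `"single"`
#'   (default; SGD is insensitive to fp32 rounding and it roughly doubles
#'   throughput) or `"double"`.
#' @param verbose print progress.
#' @return the trained `ringnav_net` (parameters with smallest validation
#'   error), with attributes `history` (data.frame of batch, training loss,
#'   validation loss) and `val_loss` (the selected validation error).
#' @export
train_network <- function(net, n_trials = 15000, batch_size = 32L,
                          lr = c(3e-4, 1e-4, 3e-5),
                          lr_breaks = c(0.38, 0.79),
                          grad_clip = 100, n_val = 500L, val_every = 2000L,
                          epochs = 84L, generator = NULL,
                          precision = c("single", "double"),
                          verbose = FALSE) {
  if (length(lr) == 1) lr_breaks <- numeric(0)
  if (is.null(lr_breaks)) lr_breaks <- seq_len(length(lr) - 1) / length(lr)
  stopifnot(length(lr_breaks) == length(lr) - 1)
  precision <- match.arg(precision)
  bptt <- if (precision == "single") cpp_rnn_bptt_f32 else cpp_rnn_bptt
  cfg <- net$cfg
  if (is.null(generator)) {
    generator <- function(n) training_cube(n, cfg, net$velocity_code)
  }
  gen_cube <- function(n) {
    g <- generator(n)
    if (is.list(g) && !is.null(g$X) && is.array(g$X)) g else
      trial_cube(g, ncol(net$Wx))
  }
  val <- gen_cube(n_val)
  pars <- c("Wx", "Wh", "b", "Wo", "bo")
  m <- v <- lapply(net[pars], function(p) p * 0)
  names(m) <- names(v) <- pars
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n_batches <- max(1L, floor(epochs * n_trials / batch_size))
  lr_of <- function(k) lr[1 + findInterval(k / n_batches, lr_breaks)]
  pool <- NULL
  phase_now <- -1L
  ks <- 0L                               # step count within the phase
  enter_phase <- function(k) {
    # each learning-rate phase resumes from the best-validation
    # parameters so far, with a fresh pool of n_trials independent
    # trials and a warm restart of the Adam moments
    phase <- findInterval(k / n_batches, lr_breaks)
    if (phase != phase_now) {
      if (phase_now >= 0L) {
        check_val(k - 1L)
        net[pars] <<- best$pars
      }
      if (epochs > 1) {
        pool <<- lapply(seq_len(max(1L, floor(n_trials / batch_size))),
                        function(i) gen_cube(batch_size))
      }
      m <<- lapply(m, function(x) x * 0)
      v <<- lapply(v, function(x) x * 0)
      ks <<- 0L
      phase_now <<- phase
    }
    ks <<- ks + 1L
  }
  best <- list(loss = Inf, pars = net[pars], batch = 0L)
  hist_b <- integer(0); hist_tl <- numeric(0); hist_vl <- numeric(0)
  check_val <- function(k) {
    vl <- cpp_rnn_loss(net$Wx, net$Wh, net$b, net$Wo, net$bo,
                       val$X, val$O, net$nonneg)
    if (vl < best$loss) best <<- list(loss = vl, pars = net[pars], batch = k)
    vl
  }
  init_val <- check_val(0L)
  for (k in seq_len(n_batches)) {
    enter_phase(k)
    tc <- if (epochs > 1) pool[[sample.int(length(pool), 1)]] else
      gen_cube(batch_size)
    g <- bptt(net$Wx, net$Wh, net$b, net$Wo, net$bo,
              tc$X, tc$O, net$nonneg)
    gs <- list(Wx = g$gWx, Wh = g$gWh, b = as.numeric(g$gb),
               Wo = g$gWo, bo = as.numeric(g$gbo))
    gn <- sqrt(sum(vapply(gs, function(x) sum(x^2), 0)))
    if (gn > grad_clip) gs <- lapply(gs, function(x) x * grad_clip / gn)
    for (p in pars) {
      m[[p]] <- beta1 * m[[p]] + (1 - beta1) * gs[[p]]
      v[[p]] <- beta2 * v[[p]] + (1 - beta2) * gs[[p]]^2
      mh <- m[[p]] / (1 - beta1^ks)
      vh <- v[[p]] / (1 - beta2^ks)
      net[[p]] <- net[[p]] - lr_of(k) * mh / (sqrt(vh) + eps)
    }
    if (k %% val_every == 0 || k == n_batches) {
      vl <- check_val(k)
      hist_b <- c(hist_b, k); hist_tl <- c(hist_tl, g$loss)
      hist_vl <- c(hist_vl, vl)
      if (verbose)
        message(sprintf("batch %d/%d  train %.5f  val %.5f  best %.5f",
                        k, n_batches, g$loss, vl, best$loss))
    }
  }
  if (best$loss >= init_val)
    warning("validation loss never improved on its initial value; ",
            "returning best parameters found")
  net[pars] <- best$pars
  attr(net, "history") <- data.frame(batch = hist_b, train_loss = hist_tl,
                                     val_loss = hist_vl)
  attr(net, "val_loss") <- best$loss
  attr(net, "init_val_loss") <- init_val
  net
}

#' Decode the network's location estimate
#'
#' The estimate at each step is the preferred location of the most active
#' output neuron; ties break toward the lowest cell index.
#'
#' @param O a `T x n_out` output activation matrix (or the list returned by
#'   [rnn_forward()]).
#' @param cfg a [sim_config()] (for the place-cell grid).
#' @return an `estimate_trace` with agent `"rnn"` (`circ_var` is `NA`; a
#'   point estimator carries no spread).
#' @export
decode_location <- function(O, cfg = sim_config()) {
  if (is.list(O) && !is.null(O$O)) O <- O$O
  z <- place_cell_grid(ncol(O))
  y_hat <- z[max.col(O, ties.method = "first")]
  new_estimate_trace(y_hat, rep(NA_real_, nrow(O)), "rnn")
}

#' Save / load a network checkpoint
#'
#' Writes a directory with a JSON manifest (scheme, variant, configuration,
#' validation loss) and one whitespace-separated text matrix per weight
#' array, a portable plain-text checkpoint format.
#'
#' @param net a `ringnav_net`.
#' @param dir checkpoint directory.
#' @return `dir` invisibly (`save_network`); a `ringnav_net`
#'   (`load_network`).
#' @export
save_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in c("Wx", "Wh", "Wo")) {
    write.table(net[[p]], file.path(dir, paste0(p, ".txt")),
                row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(scheme = net$scheme, nonneg = net$nonneg,
                   n_hidden = nrow(net$Wh), n_in = ncol(net$Wx),
                   n_out = nrow(net$Wo), b = net$b, bo = net$bo,
                   velocity_code = net$velocity_code,
                   val_loss = attr(net, "val_loss"),
                   cfg = unclass(net$cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_network
#' @export
load_network <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg_args <- man$cfg
  cfg_args$n_steps <- NULL
  cfg <- do.call(sim_config, cfg_args)
  rd <- function(p) as.matrix(read.table(file.path(dir, paste0(p, ".txt"))))
  net <- structure(list(
    Wx = unname(rd("Wx")), Wh = unname(rd("Wh")), b = man$b,
    Wo = unname(rd("Wo")), bo = man$bo, nonneg = man$nonneg,
    scheme = man$scheme, velocity_code = man$velocity_code, cfg = cfg
  ), class = "ringnav_net")
  attr(net, "val_loss") <- man$val_loss
  net
}

#' Collect network activity over a trial set
#'
#' Runs the network on each trial and stacks per-step records for the
#' population analyses: hidden states, outputs, decoded estimates, true
#' positions, task phase, landmark-input activity, and trial/step indices.
#'
#' @param net a `ringnav_net`.
#' @param trials a `trial_set`.
#' @param included_only drop trials flagged for exclusion (fewer than two
#'   different landmarks encountered).
#' @return list with matrices `H` (`N x n_hidden`), `O` (`N x n_out`) and
#'   vectors `y`, `y_hat`, `phase`, `lm_input` (logical), `trial`, `step`,
#'   plus the retained `trials`.
#' @export
collect_activity <- function(net, trials, included_only = TRUE) {
  keep <- if (included_only)
    vapply(trials, function(tr) tr$included, TRUE) else rep(TRUE, length(trials))
  trials <- trials[keep]
  if (length(trials) == 0) stop("no trials left after exclusion")
  fw <- rnn_forward_trials(net, trials)
  T <- nrow(trials[[1]]$X)
  H <- do.call(rbind, lapply(fw, `[[`, "H"))
  O <- do.call(rbind, lapply(fw, `[[`, "O"))
  y <- unlist(lapply(trials, function(tr) tr$traj$y))
  phase <- unlist(lapply(trials, function(tr) phase_labels(tr$encounters, T)))
  lm_in <- unlist(lapply(trials, function(tr)
    landmark_input_steps(tr$encounters, T)))
  est <- decode_location(O, net$cfg)
  list(H = H, O = O, y = y, y_hat = est$y_hat, phase = phase,
       lm_input = lm_in, trial = rep(seq_along(trials), each = T),
       step = rep(seq_len(T), length(trials)), trials = trials)
}
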