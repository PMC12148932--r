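# Independent reference implementations used to cross-check the package's
# computational kernels on tiny instances.

# plain-R recurrent forward pass (slow; used only on small fixtures)
ref_rnn_forward <- function(net, X) {
  T <- nrow(X)
  n_h <- nrow(net$Wh)
  H <- matrix(0, T, n_h)
  O <- matrix(0, T, nrow(net$Wo))
  h <- numeric(n_h)
  for (t in seq_len(T)) {
    p <- as.numeric(net$Wx %*% X[t, ] + net$Wh %*% h + net$b)
    if (net$nonneg) p <- pmax(p, 0)
    h <- tanh(p)
    H[t, ] <- h
    O[t, ] <- tanh(as.numeric(net$Wo %*% h + net$bo))
  }
  list(H = H, O = O)
}

ref_rnn_loss <- function(net, X, Otar) {
  O <- ref_rnn_forward(net, X)$O
  mean((O - Otar)^2)
}

# central finite-difference gradient of the trial loss wrt one parameter
ref_num_grad <- function(net, X, Otar, par, eps = 1e-6) {
  p0 <- net[[par]]
  g <- array(0, dim = if (is.matrix(p0)) dim(p0) else length(p0))
  for (i in seq_along(p0)) {
    np <- net; np[[par]][i] <- p0[i] + eps
    lp <- ref_rnn_loss(np, X, Otar)
    nm <- net; nm[[par]][i] <- p0[i] - eps
    lm <- ref_rnn_loss(nm, X, Otar)
    g[i] <- (lp - lm) / (2 * eps)
  }
  g
}

# wrapped-Gaussian kernel density of a weighted particle cloud on a grid
ref_particle_kde <- function(y, w, theta, bw) {
  dens <- vapply(theta, function(th) {
    d <- ringnav::circ_diff(th, y)
    sum(w * (dnorm(d, 0, bw) + dnorm(d - 2 * pi, 0, bw) +
               dnorm(d + 2 * pi, 0, bw)))
  }, 0)
  dens / sum(dens)
}

# sample points uniformly inside an n-dimensional unit hypercube, embedded
# in a higher-dimensional space by a random rotation
embedded_hypercube <- function(n_points, n_dim, ambient = 20L) {
  P <- matrix(runif(n_points * n_dim), n_points, n_dim)
  Q <- qr.Q(qr(matrix(rnorm(ambient * ambient), ambient)))
  cbind(P, matrix(0, n_points, ambient - n_dim)) %*% Q
}
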