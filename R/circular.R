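#' Wrap angles onto the circle
#'
#' Reduces angles to the canonical interval `[0, 2*pi)`.
#'
#' @param theta numeric vector of angles (rad).
#' @return numeric vector in `[0, 2*pi)`.
#' @export
wrap_angle <- function(theta) theta %% (2 * pi)

#' Circular distance between angles
#'
#' `circ_dist` returns the unsigned arc distance, always in `[0, pi]`.
#' `circ_diff` returns the signed difference `a - b` wrapped to `(-pi, pi]`.
#'
#' @param a,b numeric vectors of angles (rad); recycled to common length.
#' @return numeric vector of distances (rad).
#' @export
circ_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

#' @rdname circ_dist
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d - ifelse(d > pi, 2 * pi, 0)
}

#' von Mises activation bump
#'
#' The tuning-curve kernel used throughout the package for place-cell
#' targets, map inputs and landmark likelihoods:
#' `exp((cos(delta) - 1) / (2 * sigma^2))`. Equals 1 at `delta = 0` and
#' decays smoothly on the circle with width `sigma`.
#'
#' @param delta angular offset(s) from the preferred angle (rad).
#' @param sigma tuning width (rad); must be > 0.
#' @return activations in `(0, 1]`.
#' @export
vm_bump <- function(delta, sigma) {
  stopifnot(sigma > 0)
  exp((cos(delta) - 1) / (2 * sigma^2))
}

#' Weighted circular mean and circular variance
#'
#' Computes the first trigonometric moment of a set of angles. The estimate
#' is the argument of the weighted resultant vector and the circular
#' variance is one minus its length. When the resultant (numerically)
#' vanishes the mean direction is undefined: `y_hat` is returned as `NA`
#' with `circ_var = 1` and `defined = FALSE`.
#'
#' @param angles numeric vector of angles (rad).
#' @param weights nonnegative weights; uniform if `NULL`. Must not sum to 0.
#' @return list with `y_hat` (rad, possibly `NA`), `circ_var` in `[0, 1]`,
#'   and logical `defined`.
#' @export
circular_estimate <- function(angles, weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / length(angles), length(angles))
  sw <- sum(weights)
  if (!(sw > 0)) stop("weights must have positive sum")
  weights <- weights / sw
  cx <- sum(weights * cos(angles))
  sx <- sum(weights * sin(angles))
  r <- sqrt(cx^2 + sx^2)
  if (r < 1e-12) {
    list(y_hat = NA_real_, circ_var = 1, defined = FALSE)
  } else {
    list(y_hat = wrap_angle(atan2(sx, cx)), circ_var = 1 - r, defined = TRUE)
  }
}
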