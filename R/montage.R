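#' Synthetic EEG channel montage
#'
#' Places `n_channels` sensors quasi-uniformly on the upper hemisphere of a
#' 10-cm-radius head using a Fibonacci lattice. Positions are only used for
#' two purposes: building spatially correlated noise (nearby channels share
#' noise) and defining nearest-channel searchlight neighborhoods, so a
#' statistical stand-in for a real 10-10 montage is sufficient.
#'
#' @param n_channels number of channels.
#' @param radius_m head radius in meters.
#' @return data.frame with columns `name`, `x`, `y`, `z` (meters).
#' @export
synthetic_montage <- function(n_channels = 63L, radius_m = 0.1) {
  stopifnot(n_channels >= 1L)
  i <- seq_len(n_channels) - 0.5
  # upper hemisphere: polar angle in [0, pi/2]
  phi <- acos(1 - i / n_channels)
  theta <- pi * (1 + sqrt(5)) * i
  data.frame(
    name = sprintf("E%02d", seq_len(n_channels)),
    x = radius_m * sin(phi) * cos(theta),
    y = radius_m * sin(phi) * sin(theta),
    z = radius_m * cos(phi),
    stringsAsFactors = FALSE
  )
}

#' Spatially correlated channel noise covariance
#'
#' Exponential spatial correlation over sensor distance,
#' `Sigma_ij = sigma^2 * exp(-d_ij / length_scale)`, which is positive
#' definite for any sensor layout. Emulates the strong neighbor correlations
#' of real EEG noise.
#'
#' @param montage data.frame with `x`, `y`, `z` columns (meters).
#' @param length_scale correlation length (meters).
#' @param sigma marginal noise standard deviation.
#' @return Positive-definite `n x n` covariance matrix.
#' @export
spatial_noise_covariance <- function(montage, length_scale = 0.04, sigma = 1) {
  d <- as.matrix(stats::dist(montage[, c("x", "y", "z")]))
  sigma^2 * exp(-d / length_scale)
}

check_spd <- function(sigma, what = "noise_covariance") {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) {
    stop(what, " must be a square matrix")
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop(what, " must be symmetric")
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop(what, " must be positive definite")
  }
  invisible(TRUE)
}
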