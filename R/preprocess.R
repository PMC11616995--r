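#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default the 100-ms prestimulus window) from the whole epoch, so the
#' post-hoc baseline mean is zero within float tolerance.
#'
#' @param epochs a [braille_epochs] object.
#' @param window_ms baseline window (ms), must intersect the epoch time axis.
#' @return Baseline-corrected [braille_epochs].
#' @export
baseline_correct <- function(epochs, window_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "braille_epochs"))
  sel <- epochs$time_ms >= window_ms[1] & epochs$time_ms <= window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- epochs$data - as.vector(base)  # recycles over samples (dim 3)
  braille_epochs(out, epochs$time_ms, epochs$montage, epochs$labels)
}

#' Multivariate noise normalization (whitening)
#'
#' Estimates a channels x channels noise covariance within each condition at
#' each time point (patterns centered per condition, so planted condition
#' means do not inflate the noise estimate), applies analytic shrinkage
#' toward a scaled identity per estimate, averages the estimates across time
#' points and conditions, and whitens every epoch by the inverse matrix
#' square root `Sigma^(-1/2)`. Output shape equals input shape.
#'
#' @param epochs a [braille_epochs] object (>= 2 regular trials/condition).
#' @param shrinkage `"auto"` for Ledoit-Wolf-style analytic shrinkage,
#'   a number in \[0, 1\] for a fixed intensity, or `0` to disable (then a
#'   singular pooled covariance is an error).
#' @param return_matrix also attach the whitening matrix as attribute
#'   `whitener` (and the pooled covariance as `sigma`).
#' @return Whitened [braille_epochs].
#' @export
noise_normalize <- function(epochs, shrinkage = "auto", return_matrix = FALSE) {
  stopifnot(inherits(epochs, "braille_epochs"))
  sigma <- pooled_noise_covariance(epochs, shrinkage)
  w <- matrix_inv_sqrt(sigma)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[2])  # ch x (trial*sample)
  flat <- w %*% flat
  out <- aperm(array(flat, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  res <- braille_epochs(out, epochs$time_ms, epochs$montage, epochs$labels)
  if (return_matrix) {
    attr(res, "whitener") <- w
    attr(res, "sigma") <- sigma
  }
  res
}

# Condition- and time-resolved covariance estimation, shrinkage per estimate,
# averaged over conditions and time points.
pooled_noise_covariance <- function(epochs, shrinkage = "auto") {
  labs <- epochs$labels
  reg <- which(labs$kind == "regular")
  cond <- condition_index(labs$letter[reg], labs$hand[reg])
  counts <- table(cond)
  if (length(counts) == 0 || min(counts) < 2) {
    stop("need at least 2 regular trials per present condition")
  }
  n_ch <- dim(epochs$data)[2]
  n_t <- dim(epochs$data)[3]
  acc <- matrix(0, n_ch, n_ch)
  n_est <- 0L
  for (cc in as.integer(names(counts))) {
    rows <- reg[cond == cc]
    for (s in seq_len(n_t)) {
      x <- epochs$data[rows, , s, drop = TRUE]
      acc <- acc + shrink_covariance(x, shrinkage)
      n_est <- n_est + 1L
    }
  }
  acc / n_est
}

#' Shrinkage covariance estimate
#'
#' Sample covariance of the rows of `x` shrunk toward the scaled identity
#' `mean(diag(S)) * I`. With `shrinkage = "auto"` the intensity is the
#' analytic (Ledoit-Wolf) formula, clipped to \[0, 1\].
#'
#' @param x observations x variables matrix.
#' @param shrinkage `"auto"`, or a fixed intensity in \[0, 1\].
#' @return Shrunk covariance matrix.
#' @export
shrink_covariance <- function(x, shrinkage = "auto") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 observations")
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- crossprod(xc) / (n - 1)
  target <- mean(diag(s)) * diag(ncol(x))
  if (identical(shrinkage, "auto")) {
    # Ledoit-Wolf: lambda = sum_i Var(s_ij-hat) / sum_ij (s_ij - target_ij)^2
    xc2 <- xc^2
    var_s <- (crossprod(xc2) - (n - 1)^2 / n * s^2) * n / ((n - 1)^3)
    dd <- sum((s - target)^2)
    lambda <- if (dd > 0) sum(var_s) / dd else 1
    lambda <- min(1, max(0, lambda))
  } else {
    lambda <- shrinkage
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("shrinkage must be 'auto' or a number in [0, 1]")
    }
  }
  (1 - lambda) * s + lambda * target
}

#' Inverse matrix square root
#'
#' `Sigma^(-1/2)` via symmetric eigendecomposition. Errors on (numerically)
#' singular input rather than silently regularizing.
#'
#' @param sigma symmetric positive-definite matrix.
#' @return Symmetric matrix `W` with `W %*% sigma %*% W == I`.
#' @export
matrix_inv_sqrt <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values)) {
    stop("covariance is singular; enable shrinkage")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Average trials into pseudo-trials
#'
#' Randomly partitions the trials of one condition into disjoint bins of
#' `bin_size` and averages each bin into one pseudo-trial; leftover trials
#' are dropped. With 170 trials and bin 34 this yields the 5 pseudo-trials
#' entering fivefold cross-validation.
#'
#' @param x trials x features matrix (one condition's trials).
#' @param bin_size trials per bin (>= 1, <= nrow(x)).
#' @param seed RNG seed for the random assignment.
#' @return Matrix `floor(nrow(x)/bin_size) x features` of class
#'   `pseudo_trials`, with the bin membership (a list of source-row index
#'   vectors) in attribute `members`.
#' @export
bin_pseudotrials <- function(x, bin_size, seed = NULL) {
  x <- as.matrix(x)
  if (bin_size < 1) stop("bin_size must be at least 1")
  n <- nrow(x)
  if (n < bin_size) stop("need at least bin_size trials")
  k <- n %/% bin_size
  with_seed(seed, {
    ord <- sample.int(n)
    members <- lapply(seq_len(k), function(i) {
      sort(ord[((i - 1) * bin_size + 1):(i * bin_size)])
    })
    out <- do.call(rbind, lapply(members, function(m) {
      colMeans(x[m, , drop = FALSE])
    }))
    attr(out, "members") <- members
    class(out) <- c("pseudo_trials", class(out))
    out
  })
}

#' Average runs into five pseudo-runs
#'
#' Applies [bin_pseudotrials] run-wise to every condition of a pattern set
#' with `bin_size = floor(n_runs / 5)`, so each condition ends up with
#' exactly 5 pseudo-run patterns (10 runs -> bins of 2; 25 runs -> bins of
#' 5; leftover runs are dropped). The random run-to-bin assignment is shared
#' across conditions and features, as a run is reassigned as a whole.
#'
#' @param pattern_set a `pattern_set` (array `runs x 16 x features`).
#' @param seed RNG seed.
#' @return Array `16 x 5 x features` (condition x pseudo-run x feature) with
#'   attribute `members` (run indices per bin).
#' @export
bin_pseudoruns <- function(pattern_set, seed = NULL) {
  data <- if (inherits(pattern_set, "pattern_set")) pattern_set$data else pattern_set
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == 16L)
  n_runs <- dim(data)[1]
  if (n_runs < 5L) stop("need at least 5 runs to form 5 pseudo-runs")
  bin <- n_runs %/% 5L
  with_seed(seed, {
    ord <- sample.int(n_runs)
    members <- lapply(seq_len(5L), function(i) {
      sort(ord[((i - 1) * bin + 1):(i * bin)])
    })
    out <- array(0, dim = c(16L, 5L, dim(data)[3]))
    for (p in seq_len(5L)) {
      out[, p, ] <- apply(data[members[[p]], , , drop = FALSE], c(2, 3), mean)
    }
    attr(out, "members") <- members
    out
  })
}
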