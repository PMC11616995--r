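#' Specification of the planted sensory and perceptual letter codes
#'
#' The generator plants two separable codes into synthetic brain data:
#'
#' * a *sensory* code: one pattern per (hand, letter) combination, switched on
#'   from `sensory_onset_ms`. It does not transfer across hands, so it drives
#'   within-hand but not across-hand decoding.
#' * a *perceptual* code: one pattern per letter, shared by both hands,
#'   switched on from `perceptual_onset_ms`. It transfers across hands and
#'   drives both schemes.
#'
#' Perceptual patterns are embedded so that their pairwise distances realize
#' `letter_geometry` (entries are treated as squared Euclidean distances
#' between latent letter codes; the default geometry is the braille pin-overlap
#' Hamming distance, for which this embedding is exact). Noise is Gaussian
#' with covariance `noise_covariance` (spatially correlated across channels),
#' white in time by default, optionally AR(1) via `noise_ar`.
#'
#' @param sensory_onset_ms,perceptual_onset_ms onset of each code (ms after
#'   stimulus onset). Defaults place the sensory code first, as in tactile
#'   processing; the constructor permits (but messages on) a reversed order.
#' @param sensory_snr,perceptual_snr amplitude of each code relative to the
#'   unit-variance channel noise (0 disables the code).
#' @param effect_duration_ms how long each code stays on after its onset.
#' @param noise_covariance channels x channels positive-definite matrix, or
#'   NULL to build a spatially correlated default from the montage at
#'   synthesis time.
#' @param noise_ar AR(1) coefficient of the channel noise over time samples
#'   (0 = temporally white; the stationary marginal covariance is preserved).
#' @param letter_geometry symmetric 8x8 latent letter dissimilarity.
#' @param seed master seed for all pattern and noise draws of this spec.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(sensory_onset_ms = 80, perceptual_onset_ms = 180,
                        sensory_snr = 1, perceptual_snr = 1,
                        effect_duration_ms = 600,
                        noise_covariance = NULL, noise_ar = 0,
                        letter_geometry = braille_letter_geometry(),
                        seed = 1L) {
  if (!is.null(noise_covariance)) check_spd(noise_covariance)
  if (!is.matrix(letter_geometry) || !all(dim(letter_geometry) == 8L)) {
    stop("letter_geometry must be an 8x8 matrix")
  }
  if (max(abs(letter_geometry - t(letter_geometry))) > 1e-8) {
    stop("letter_geometry must be symmetric")
  }
  if (noise_ar < 0 || noise_ar >= 1) stop("noise_ar must be in [0, 1)")
  if (sensory_onset_ms > perceptual_onset_ms) {
    message("note: sensory onset after perceptual onset (defaults plant sensory first)")
  }
  structure(
    list(
      sensory_onset_ms = sensory_onset_ms,
      perceptual_onset_ms = perceptual_onset_ms,
      sensory_snr = sensory_snr, perceptual_snr = perceptual_snr,
      effect_duration_ms = effect_duration_ms,
      noise_covariance = noise_covariance, noise_ar = noise_ar,
      letter_geometry = letter_geometry, seed = as.integer(seed)
    ),
    class = "effect_spec"
  )
}

#' The 16 experimental conditions in canonical order
#'
#' Condition index `(hand - 1) * 8 + letter`, i.e. conditions 1-8 are the
#' eight letters read with the left hand, 9-16 with the right hand. All
#' pattern containers and the decoding engine use this order.
#'
#' @return data.frame with columns `cond`, `letter`, `hand`.
#' @export
condition_table <- function() {
  data.frame(
    cond = 1:16,
    letter = rep(braille_letters(), 2),
    hand = rep(c("left", "right"), each = 8),
    stringsAsFactors = FALSE
  )
}

condition_index <- function(letter, hand) {
  li <- match(letter, braille_letters())
  hi <- match(hand, c("left", "right"))
  (hi - 1L) * 8L + li
}

# Draw the planted pattern matrices for a given feature dimensionality.
#
# Sensory: 16 x f, one unit-norm random pattern per (hand, letter). With
# f >= 16 the patterns form a random orthonormal frame — in the metric the
# decoder sees: if the noise covariance `sigma` is supplied, frames are
# orthonormal after whitening by sigma^(-1/2) (i.e. P = U sigma^(1/2) with
# orthonormal U), so any within-hand pattern contrast is exactly orthogonal
# to every other-hand pattern in whitened space and the hand-specific code
# carries zero across-hand transfer, deterministically, as the
# sensory/perceptual operationalization requires. (Merely independent
# spherical draws leak across hands per subject through chance alignments
# of order 1/sqrt(f), which at high SNR is decodable.) Below 16 features
# orthogonality is impossible and unit-norm spherical draws are used.
#
# Perceptual: 8 x f, classical-MDS embedding of the letter geometry (entries
# read as squared Euclidean distances) rotated into feature space by a random
# orthonormal map (mapped through sigma^(1/2) likewise, so the whitened
# patterns realize the geometry exactly) and scaled to unit mean norm in
# that space, so pairwise pattern distances are a monotone transform of the
# geometry.
draw_condition_patterns <- function(spec, n_features, sigma = NULL) {
  half <- NULL
  if (!is.null(sigma)) {
    e <- eigen(sigma, symmetric = TRUE)
    half <- e$vectors %*% (t(e$vectors) * sqrt(e$values))
  }
  with_seed(split_seed(spec$seed, "patterns"), {
    if (n_features >= 16L) {
      P <- t(qr.Q(qr(matrix(rnorm(n_features * 16), n_features, 16))))
    } else {
      P <- matrix(rnorm(16 * n_features), 16, n_features)
      P <- P / sqrt(rowSums(P^2))
    }
    if (!is.null(half)) P <- P %*% half
    d <- sqrt(pmax(spec$letter_geometry, 0))
    if (max(d) == 0) {
      Q <- matrix(0, 8, n_features)
    } else {
      if (isTRUE(all.equal(unname(spec$letter_geometry),
                           unname(braille_letter_geometry() * 1.0)))) {
        # pin-overlap geometry: the centered pin patterns ARE an exact
        # Euclidean embedding (squared distance = Hamming), ties included
        coords <- scale(braille_pin_patterns(), center = TRUE, scale = FALSE)
      } else {
        k <- min(7L, n_features)
        # k may exceed the true embedding rank; cmdscale then warns and
        # returns the positive-eigen dims
        mds <- suppressWarnings(stats::cmdscale(as.dist(d), k = k, eig = TRUE))
        coords <- mds$points[, mds$eig[seq_len(ncol(mds$points))] > 1e-9,
                             drop = FALSE]
      }
      if (ncol(coords) > n_features) {
        # fewer features than embedding dims: keep the top principal axes
        coords <- stats::prcomp(coords, center = FALSE)$x[, seq_len(n_features),
                                                          drop = FALSE]
      }
      basis <- qr.Q(qr(matrix(rnorm(n_features * ncol(coords)), n_features)))
      basis <- basis[, seq_len(ncol(coords)), drop = FALSE]
      Q <- coords %*% t(basis)
      Q <- Q / sqrt(mean(rowSums(Q^2)))
      if (!is.null(half)) Q <- Q %*% half
    }
    list(sensory = P, perceptual = Q)
  })
}
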