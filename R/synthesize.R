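#' Synthesize EEG-like epochs with planted letter codes
#'
#' Generates one epoch per schedule trial under the generative model
#' \deqn{x(trial, t) = noise(t) + [t \ge t_s] \cdot a_s P_{hand,letter}
#'                              + [t \ge t_p] \cdot a_p Q_{letter}}
#' where `P` are hand-specific (sensory) patterns, `Q` hand-independent
#' (perceptual) patterns shaped by the spec's letter geometry, both switched
#' off again after `effect_duration_ms`. Noise has the spec's channel
#' covariance and is white in time (optionally AR(1)). Catch trials carry
#' noise only and stay flagged in the labels; null trials have no epoch.
#'
#' @param schedule an EEG [trial_schedule].
#' @param spec an [effect_spec]; all randomness derives from `spec$seed`.
#' @param n_channels number of channels.
#' @param srate sampling rate (Hz).
#' @param epoch_window_ms epoch window (ms), must contain 0 (stimulus onset).
#' @param montage channel montage; default [synthetic_montage].
#' @return A [braille_epochs] object.
#' @export
synthesize_eeg_epochs <- function(schedule, spec,
                                  n_channels = 63L, srate = 1000,
                                  epoch_window_ms = c(-100, 999),
                                  montage = synthetic_montage(n_channels)) {
  stopifnot(inherits(spec, "effect_spec"))
  if (!identical(attr(schedule, "modality"), "eeg")) {
    stop("schedule must be an EEG schedule")
  }
  if (epoch_window_ms[1] > 0 || epoch_window_ms[2] < 0) {
    stop("epoch_window_ms must contain 0 (stimulus onset)")
  }
  step <- 1000 / srate
  time_ms <- seq(epoch_window_ms[1], epoch_window_ms[2], by = step)
  n_samples <- length(time_ms)

  keep <- schedule$kind %in% c("regular", "catch")
  labels <- data.frame(
    trial = seq_len(sum(keep)),
    kind = schedule$kind[keep],
    letter = schedule$letter[keep],
    hand = schedule$hand[keep],
    stringsAsFactors = FALSE
  )
  n_trials <- nrow(labels)

  sigma <- spec$noise_covariance
  if (is.null(sigma)) sigma <- spatial_noise_covariance(montage)
  if (!all(dim(sigma) == n_channels)) {
    stop("noise covariance dimension does not match n_channels")
  }
  check_spd(sigma)
  cf <- chol(sigma)

  pat <- draw_condition_patterns(spec, n_channels, sigma = sigma)
  on_s <- time_ms >= spec$sensory_onset_ms &
    time_ms < spec$sensory_onset_ms + spec$effect_duration_ms
  on_p <- time_ms >= spec$perceptual_onset_ms &
    time_ms < spec$perceptual_onset_ms + spec$effect_duration_ms

  data <- array(0, dim = c(n_trials, n_channels, n_samples))
  with_seed(split_seed(spec$seed, "noise"), {
    for (tr in seq_len(n_trials)) {
      z <- matrix(rnorm(n_samples * n_channels), n_samples, n_channels)
      if (spec$noise_ar > 0) {
        a <- spec$noise_ar
        for (s in 2:n_samples) z[s, ] <- a * z[s - 1, ] + sqrt(1 - a^2) * z[s, ]
      }
      noise <- z %*% cf  # samples x channels
      epoch <- t(noise)  # channels x samples
      if (labels$kind[tr] == "regular") {
        ci <- condition_index(labels$letter[tr], labels$hand[tr])
        li <- match(labels$letter[tr], braille_letters())
        if (spec$sensory_snr != 0 && any(on_s)) {
          epoch[, on_s] <- epoch[, on_s] + spec$sensory_snr * pat$sensory[ci, ]
        }
        if (spec$perceptual_snr != 0 && any(on_p)) {
          epoch[, on_p] <- epoch[, on_p] + spec$perceptual_snr * pat$perceptual[li, ]
        }
      }
      data[tr, , ] <- epoch
    }
  })
  braille_epochs(data, time_ms, montage, labels)
}

#' Simulate one subject's epochs with a balanced mini-session
#'
#' Convenience wrapper: builds a catch-free EEG schedule with
#' `trials_per_condition` repetitions of each of the 16 conditions and
#' synthesizes epochs from it. The subject's patterns and noise derive from
#' `seed`; pass different seeds for different subjects.
#'
#' @param spec an [effect_spec] (its `seed` is replaced by `seed`).
#' @param trials_per_condition regular trials per condition.
#' @param seed subject-level seed.
#' @inheritParams synthesize_eeg_epochs
#' @return A [braille_epochs] object.
#' @export
simulate_subject_epochs <- function(spec, trials_per_condition = 20L, seed = 1L,
                                    n_channels = 16L, srate = 100,
                                    epoch_window_ms = c(-100, 390),
                                    montage = synthetic_montage(n_channels)) {
  spec$seed <- as.integer(seed)
  sched <- generate_eeg_session_schedule(
    composition = c(regular = 16L * trials_per_condition, catch = 0L),
    seed = split_seed(seed, "schedule")
  )
  synthesize_eeg_epochs(sched, spec, n_channels = n_channels, srate = srate,
                        epoch_window_ms = epoch_window_ms, montage = montage)
}

#' Synthesize fMRI-like ROI pattern sets
#'
#' Per ROI, per run and condition, a t-value-like feature vector
#' `mix * a_s * P[hand,letter] + (1 - mix) * a_p * Q[letter] + noise`,
#' where `mix` in \[0, 1\] sets how hand-dependent the ROI's letter code is
#' (1 = purely sensory, e.g. somatosensory cortex; 0 = purely perceptual,
#' e.g. sighted reading areas; intermediate = mixed, e.g. LOC).
#'
#' @param n_runs number of experimental runs (>= 5, to form 5 pseudo-runs).
#' @param spec an [effect_spec] (onsets are irrelevant here; `sensory_snr`,
#'   `perceptual_snr`, `letter_geometry` and `seed` are used).
#' @param n_features features (voxels) per ROI.
#' @param mixes named numeric vector of hand-dependence mixes, one per ROI.
#' @param noise_sd run-level pattern noise SD.
#' @return Named list of `pattern_set` objects: arrays
#'   `runs x 16 conditions x features` with the canonical condition order.
#' @export
synthesize_roi_patterns <- function(n_runs = 10L, spec = effect_spec(),
                                    n_features = 60L,
                                    mixes = default_roi_mixes(),
                                    noise_sd = 1) {
  if (n_runs < 5L) stop("n_runs must be at least 5 to form 5 pseudo-runs")
  if (any(mixes < 0 | mixes > 1)) stop("mixes must lie in [0, 1]")
  ct <- condition_table()
  out <- lapply(seq_along(mixes), function(r) {
    roi_seed <- split_seed(spec$seed, paste0("roi_", names(mixes)[r]))
    spec_r <- spec
    spec_r$seed <- roi_seed
    pat <- draw_condition_patterns(spec_r, n_features)
    mix <- mixes[[r]]
    mean_pat <- mix * spec$sensory_snr * pat$sensory +
      (1 - mix) * spec$perceptual_snr *
        pat$perceptual[match(ct$letter, braille_letters()), , drop = FALSE]
    with_seed(split_seed(roi_seed, "noise"), {
      data <- array(rnorm(n_runs * 16 * n_features, sd = noise_sd),
                    dim = c(n_runs, 16, n_features))
      for (cond in 1:16) {
        data[, cond, ] <- data[, cond, ] +
          matrix(mean_pat[cond, ], n_runs, n_features, byrow = TRUE)
      }
      structure(list(data = data, roi = names(mixes)[r]), class = "pattern_set")
    })
  })
  names(out) <- names(mixes)
  out
}

#' Default ROI hand-dependence mixes
#'
#' Emulates the qualitative regional profile of braille letter codes: tactile
#' processing regions carry a hand-dependent code, sighted reading regions a
#' hand-independent code, and the lateral occipital complex both.
#'
#' @return Named numeric vector in \[0, 1\].
#' @export
default_roi_mixes <- function() {
  c(S1 = 1, S2 = 1, aIPS = 1, pIPS = 1, insula = 0,
    EVC = 0, V4 = 0, LOC = 0.5, LFA = 0, VWFA = 0)
}

#' Synthesize behavioral letter-similarity ratings
#'
#' Each participant rates each of the 28 letter pairs on an integer scale from
#' 1 (very similar) to 7 (very different). Ratings are a monotone linear
#' rescaling of the latent pair dissimilarity to \[1, 7\] plus Gaussian noise,
#' rounded and clipped; with `noise_sd = 0`, the participant-average rating
#' RDM rank-correlates perfectly with the planted geometry.
#'
#' @param letter_geometry symmetric 8x8 latent dissimilarity.
#' @param n_participants number of raters (>= 1).
#' @param noise_sd rating noise SD (rating-scale units).
#' @param seed RNG seed.
#' @return Integer matrix `participants x 28` of class `similarity_ratings`,
#'   columns in [letter_pairs] order.
#' @export
synthesize_similarity_ratings <- function(letter_geometry = braille_letter_geometry(),
                                          n_participants = 19L, noise_sd = 1,
                                          seed = NULL) {
  if (n_participants < 1L) stop("n_participants must be at least 1")
  pairs <- letter_pairs()
  g <- letter_geometry[cbind(pairs$ia, pairs$ib)]
  if (max(g) > min(g)) {
    base <- 1 + 6 * (g - min(g)) / (max(g) - min(g))
  } else {
    base <- rep(4, length(g))  # degenerate geometry: everything mid-scale
  }
  with_seed(seed, {
    noise <- matrix(rnorm(n_participants * 28, sd = noise_sd), n_participants, 28)
    ratings <- round(sweep(noise, 2, base, "+"))
    ratings <- pmin(pmax(ratings, 1), 7)
    storage.mode(ratings) <- "integer"
    colnames(ratings) <- paste0(pairs$a, pairs$b)
    structure(ratings, class = c("similarity_ratings", "matrix"))
  })
}
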