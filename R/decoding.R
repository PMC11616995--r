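#' Pairwise cross-validated SVM decoding of one letter pair
#'
#' Fivefold leave-one-pseudo-trial-out cross-validation of a linear
#' soft-margin C-SVC. Training folds always come from `pseudo_a` /
#' `pseudo_b`; the held-out fold is taken from `test_a` / `test_b`, which
#' default to the training data (within-hand scheme) but may be the other
#' hand's pseudo-trials (across-hand scheme).
#'
#' @param pseudo_a,pseudo_b `n_pseudo x features` matrices, one row per
#'   pseudo-trial, for the two letters (classes).
#' @param test_a,test_b matrices with the same shape providing the held-out
#'   fold per CV iteration.
#' @param C SVM cost parameter (soft margin).
#' @return Mean accuracy over folds, in % (chance 50).
#' @export
pairwise_cv_decode <- function(pseudo_a, pseudo_b,
                               test_a = pseudo_a, test_b = pseudo_b,
                               C = 1) {
  pseudo_a <- as.matrix(pseudo_a); pseudo_b <- as.matrix(pseudo_b)
  test_a <- as.matrix(test_a); test_b <- as.matrix(test_b)
  k <- nrow(pseudo_a)
  if (nrow(pseudo_b) != k || nrow(test_a) != k || nrow(test_b) != k) {
    stop("all four inputs must have the same number of pseudo-trials")
  }
  if (k < 2) stop("need at least 2 pseudo-trials per condition")
  f <- ncol(pseudo_a)
  if (ncol(pseudo_b) != f || ncol(test_a) != f || ncol(test_b) != f) {
    stop("mismatched feature dimensionality")
  }
  acc <- numeric(k)
  for (p in seq_len(k)) {
    Xtr <- rbind(pseudo_a[-p, , drop = FALSE], pseudo_b[-p, , drop = FALSE])
    ytr <- rep(c(1, -1), each = k - 1)
    fit <- cpp_svm_linear(Xtr, ytr, rbind(test_a[p, ], test_b[p, ]), C = C)
    acc[p] <- 100 * mean(c(fit$decision[1] > 0, fit$decision[2] <= 0))
  }
  mean(acc)
}

pseudo_to_matrix <- function(pseudo_array) {
  stopifnot(length(dim(pseudo_array)) == 3L,
            dim(pseudo_array)[1] == 16L, dim(pseudo_array)[2] == 5L)
  matrix(aperm(pseudo_array, c(3, 2, 1)), nrow = dim(pseudo_array)[3])
}

new_decoding_result <- function(scheme, acc, time_ms = NULL, roi = NULL, meta = list()) {
  structure(list(scheme = scheme, acc = acc, time_ms = time_ms, roi = roi,
                 meta = meta),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> scheme=%s, grand mean=%.1f%%\n",
              x$scheme, grand_average(x)))
  invisible(x)
}

#' Within-hand pairwise decoding of a pseudo-trial set
#'
#' Runs all 28 letter-pair classifications separately per hand with fivefold
#' leave-one-pseudo-trial-out CV; training and held-out data come from the
#' same hand.
#'
#' @param pseudo_array `16 x 5 x features` array (condition x pseudo-trial x
#'   feature, canonical condition order).
#' @param C SVM cost parameter.
#' @return A `decoding_result` with `scheme = "within"` and `acc` a
#'   `2 (hand) x 28 (pair)` accuracy matrix in %.
#' @export
within_hand_decode <- function(pseudo_array, C = 1) {
  res <- cpp_pairwise_set(pseudo_to_matrix(pseudo_array), C = C,
                          do_within = TRUE, do_across = FALSE)
  acc <- res$within
  dimnames(acc) <- list(hand = c("left", "right"), pair = pair_names())
  new_decoding_result("within", acc, meta = list(n_folds = 5, C = C))
}

#' Across-hand pairwise decoding of a pseudo-trial set
#'
#' Same fold skeleton as [within_hand_decode], but the held-out fold is drawn
#' from the other hand's pseudo-trials; both training-testing directions are
#' computed.
#'
#' @inheritParams within_hand_decode
#' @return A `decoding_result` with `scheme = "across"` and `acc` a
#'   `2 (direction: trained left / trained right) x 28` matrix in %.
#' @export
across_hand_decode <- function(pseudo_array, C = 1) {
  res <- cpp_pairwise_set(pseudo_to_matrix(pseudo_array), C = C,
                          do_within = FALSE, do_across = TRUE)
  acc <- res$across
  dimnames(acc) <- list(direction = c("train_left", "train_right"),
                        pair = pair_names())
  new_decoding_result("across", acc, meta = list(n_folds = 5, C = C))
}

pair_names <- function() {
  p <- letter_pairs()
  paste0(p$a, p$b)
}

#' Sensory score: within-hand minus across-hand accuracy
#'
#' Entrywise difference of hand-averaged within-hand and direction-averaged
#' across-hand accuracies; isolates the hand-dependent (sensory) letter code
#' and is compared against 0 downstream.
#'
#' @param within,across `decoding_result`s with matching pair/time layout.
#' @return A `decoding_result` with `scheme = "difference"`; `acc` is
#'   `28 x ...` (pairs, then any time dimension), in percentage points.
#' @export
sensory_score <- function(within, across) {
  stopifnot(within$scheme == "within", across$scheme == "across")
  w <- hand_average(within)
  x <- hand_average(across)
  if (!identical(dim(w), dim(x)) || !identical(length(w), length(x))) {
    stop("within and across results have mismatched shapes")
  }
  new_decoding_result("difference", w - x, time_ms = within$time_ms,
                      roi = within$roi,
                      meta = c(within$meta, list(chance = 0)))
}

#' Average a decoding result over hands (or training directions)
#'
#' @param result a `decoding_result` with a leading hand/direction dimension.
#' @return Pair-resolved accuracies: vector of 28 (ROI case) or `28 x time`
#'   matrix (time-resolved case). `difference` results are returned as-is.
#' @export
hand_average <- function(result) {
  if (result$scheme == "difference") return(result$acc)
  a <- result$acc
  if (length(dim(a)) == 2L) colMeans(a)
  else apply(a, c(2, 3), mean)
}

#' Grand-average accuracy of a decoding result
#'
#' Mean over all pairs, hands/directions and (if present) time points.
#' @param result a `decoding_result`.
#' @return Scalar accuracy in % (or percentage points for `difference`).
#' @export
grand_average <- function(result) mean(result$acc, na.rm = TRUE)

#' Time-resolved pairwise decoding of epochs
#'
#' For every sample of the (preprocessed) epochs, forms `n_pseudo`
#' pseudo-trials per condition by random disjoint binning, runs all 28
#' pairwise fivefold CV classifications within-hand and/or across-hand, and
#' repeats the whole procedure `n_iterations` times with fresh random
#' assignments, averaging accuracies over folds and iterations.
#'
#' @param epochs a [braille_epochs] object with all 16 conditions present.
#' @param n_iterations pseudo-trial assignment repetitions.
#' @param n_pseudo pseudo-trials per condition (5 gives fivefold CV).
#' @param seed RNG seed for the assignments.
#' @param C SVM cost parameter.
#' @param schemes which schemes to compute.
#' @return List with elements `within` and/or `across` (`decoding_result`s
#'   whose `acc` is `2 x 28 x n_samples`), plus `time_ms`.
#' @export
time_resolved_decode <- function(epochs, n_iterations = 100, n_pseudo = 5,
                                 seed = NULL, C = 1,
                                 schemes = c("within", "across")) {
  stopifnot(inherits(epochs, "braille_epochs"))
  schemes <- match.arg(schemes, several.ok = TRUE)
  epochs <- regular_trials(epochs)
  cond <- condition_index(epochs$labels$letter, epochs$labels$hand)
  if (length(unique(cond)) < 16L) stop("all 16 conditions must be present")
  cube <- aperm(epochs$data, c(2, 3, 1))  # channels x samples x trials
  res <- with_seed(seed, {
    cpp_time_resolved(cube, as.integer(cond),
                      n_iterations = as.integer(n_iterations),
                      n_pseudo = as.integer(n_pseudo), C = C,
                      do_within = "within" %in% schemes,
                      do_across = "across" %in% schemes)
  })
  meta <- list(n_folds = 5, n_iterations = n_iterations,
               bin_size = res$bin_size, C = C)
  out <- list(time_ms = epochs$time_ms)
  if ("within" %in% schemes) {
    out$within <- new_decoding_result("within", res$within,
                                      time_ms = epochs$time_ms, meta = meta)
  }
  if ("across" %in% schemes) {
    out$across <- new_decoding_result("across", res$across,
                                      time_ms = epochs$time_ms, meta = meta)
  }
  out
}

#' ROI-wise decoding of fMRI-like pattern sets
#'
#' Bins each ROI's runs into 5 pseudo-runs, then computes within-hand,
#' across-hand and difference results per ROI.
#'
#' @param pattern_sets named list of `pattern_set`s
#'   (see [synthesize_roi_patterns]).
#' @param seed RNG seed for the run-to-bin assignment.
#' @param n_iterations pseudo-run assignment repetitions (the run-wise
#'   analysis is commonly done once; more iterations only reduce binning
#'   noise).
#' @param C SVM cost parameter.
#' @return Named list (per ROI) of lists with `within`, `across`,
#'   `difference` `decoding_result`s.
#' @export
roi_decode <- function(pattern_sets, seed = NULL, n_iterations = 1, C = 1) {
  stopifnot(is.list(pattern_sets))
  with_seed(seed, {
    out <- lapply(names(pattern_sets), function(roi) {
      w_acc <- matrix(0, 2, 28)
      x_acc <- matrix(0, 2, 28)
      for (it in seq_len(n_iterations)) {
        pseudo <- bin_pseudoruns(pattern_sets[[roi]])
        res <- cpp_pairwise_set(pseudo_to_matrix(pseudo), C = C)
        w_acc <- w_acc + res$within
        x_acc <- x_acc + res$across
      }
      w <- new_decoding_result("within", w_acc / n_iterations, roi = roi,
                               meta = list(n_folds = 5, C = C,
                                           n_iterations = n_iterations))
      x <- new_decoding_result("across", x_acc / n_iterations, roi = roi,
                               meta = list(n_folds = 5, C = C,
                                           n_iterations = n_iterations))
      dimnames(w$acc) <- list(hand = c("left", "right"), pair = pair_names())
      dimnames(x$acc) <- list(direction = c("train_left", "train_right"),
                              pair = pair_names())
      list(within = w, across = x, difference = sensory_score(w, x))
    })
    names(out) <- names(pattern_sets)
    out
  })
}

#' Simulate and decode a group of subjects, time-resolved
#'
#' Convenience driver for simulation studies: for each subject, synthesizes
#' epochs from `spec` (subject-specific pattern/noise seeds split from
#' `seed`), preprocesses them (baseline correction + multivariate noise
#' normalization), and runs [time_resolved_decode].
#'
#' @param n_subjects number of subjects.
#' @param spec an [effect_spec] shared by the group.
#' @param seed master seed (subject streams are split from it).
#' @param trials_per_condition,n_channels,srate,epoch_window_ms passed to
#'   [simulate_subject_epochs].
#' @param n_iterations,n_pseudo,C passed to [time_resolved_decode].
#' @param schemes which schemes to compute.
#' @param keep_pairs also return pair-resolved accuracies (needed for RSA).
#' @return List with `time_ms`, and per scheme a `subjects x time` matrix of
#'   pair- and hand-averaged accuracies (`within`, `across`, `difference`);
#'   with `keep_pairs`, also `within_pairs` / `across_pairs` arrays
#'   (`subjects x 28 x time`).
#' @export
decode_group_time_courses <- function(n_subjects, spec, seed = 1L,
                                      trials_per_condition = 20L,
                                      n_channels = 16L, srate = 100,
                                      epoch_window_ms = c(-100, 390),
                                      n_iterations = 10L, n_pseudo = 5L, C = 1,
                                      schemes = c("within", "across"),
                                      keep_pairs = FALSE) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  time_ms <- NULL
  within <- NULL; across <- NULL
  within_pairs <- NULL; across_pairs <- NULL
  for (s in seq_len(n_subjects)) {
    ep <- simulate_subject_epochs(spec,
                                  trials_per_condition = trials_per_condition,
                                  seed = split_seed(seed, s),
                                  n_channels = n_channels, srate = srate,
                                  epoch_window_ms = epoch_window_ms)
    ep <- noise_normalize(baseline_correct(ep))
    dec <- time_resolved_decode(ep, n_iterations = n_iterations,
                                n_pseudo = n_pseudo,
                                seed = split_seed(seed, 10000 + s), C = C,
                                schemes = schemes)
    if (is.null(time_ms)) {
      time_ms <- dec$time_ms
      nt <- length(time_ms)
      if ("within" %in% schemes) within <- matrix(NA_real_, n_subjects, nt)
      if ("across" %in% schemes) across <- matrix(NA_real_, n_subjects, nt)
      if (keep_pairs) {
        if ("within" %in% schemes) within_pairs <- array(NA_real_, c(n_subjects, 28, nt))
        if ("across" %in% schemes) across_pairs <- array(NA_real_, c(n_subjects, 28, nt))
      }
    }
    if ("within" %in% schemes) {
      pa <- hand_average(dec$within)
      within[s, ] <- colMeans(pa)
      if (keep_pairs) within_pairs[s, , ] <- pa
    }
    if ("across" %in% schemes) {
      pa <- hand_average(dec$across)
      across[s, ] <- colMeans(pa)
      if (keep_pairs) across_pairs[s, , ] <- pa
    }
  }
  out <- list(time_ms = time_ms)
  if (!is.null(within)) out$within <- within
  if (!is.null(across)) out$across <- across
  if (!is.null(within) && !is.null(across)) out$difference <- within - across
  if (keep_pairs) {
    out$within_pairs <- within_pairs
    out$across_pairs <- across_pairs
  }
  out
}
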