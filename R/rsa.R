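#' Representational dissimilarity matrices (RDMs)
#'
#' An RDM is a symmetric 8x8 matrix over the regular braille letters with an
#' undefined (NA) diagonal. Entries are either pairwise decoding accuracies
#' (%) — higher accuracy meaning more dissimilar neural patterns — or mean
#' similarity ratings (1 = very similar .. 7 = very different).
#'
#' @param values vector of 28 pair values in [letter_pairs] order, or a full
#'   symmetric 8x8 matrix.
#' @param source free-form provenance tag (e.g. "eeg@200ms", "behavior").
#' @return An object of class `rdm` (an 8x8 matrix with letter dimnames).
#' @export
rdm <- function(values, source = NULL) {
  L <- braille_letters()
  if (is.matrix(values)) {
    stopifnot(all(dim(values) == 8L))
    m <- values
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) stop("RDM must be symmetric")
  } else {
    if (length(values) != 28L) stop("need 28 pair values")
    m <- matrix(NA_real_, 8, 8)
    p <- letter_pairs()
    m[cbind(p$ia, p$ib)] <- values
    m[cbind(p$ib, p$ia)] <- values
  }
  diag(m) <- NA_real_
  dimnames(m) <- list(L, L)
  structure(m, class = c("rdm", "matrix"), source = source)
}

#' Lower-triangle vectorization of an RDM
#' @param x an [rdm] (or any 8x8 symmetric matrix).
#' @return The 28 below-diagonal entries in [letter_pairs] order.
#' @export
rdm_vec <- function(x) {
  p <- letter_pairs()
  unclass(x)[cbind(p$ib, p$ia)]
}

#' Build an RDM from pairwise decoding accuracies
#'
#' Decoding accuracy is read as a dissimilarity: letter pairs that are easier
#' to classify apart have more dissimilar neural patterns. Accuracies are
#' averaged over hands (within scheme) or training-testing directions
#' (across scheme) before entering the RDM.
#'
#' @param decoding_result a `decoding_result` whose `acc` covers all 28 pairs
#'   (a `2 x 28` matrix, or `2 x 28 x time` — then `time_index` selects the
#'   time point).
#' @param time_index sample index for time-resolved results.
#' @return An [rdm] with % accuracy entries.
#' @export
accuracies_to_rdm <- function(decoding_result, time_index = NULL) {
  acc <- hand_average(decoding_result)
  if (!is.null(dim(acc)) && length(dim(acc)) == 2L) {
    if (is.null(time_index)) stop("time-resolved result: give time_index")
    acc <- acc[, time_index]
  }
  if (length(acc) != 28L || anyNA(acc)) stop("need a full 28-pair accuracy set")
  src <- paste0(decoding_result$scheme,
                if (!is.null(decoding_result$roi)) paste0("@", decoding_result$roi))
  rdm(acc, source = src)
}

#' Build an RDM from behavioral similarity ratings
#'
#' Participant-averaged pair ratings arranged in RDM layout.
#'
#' @param ratings `participants x 28` matrix (see
#'   [synthesize_similarity_ratings]); values must lie in \[1, 7\].
#' @return An [rdm] with mean-rating entries.
#' @export
ratings_to_rdm <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 28L) stop("ratings must have 28 pair columns")
  if (nrow(ratings) < 1L) stop("need at least one participant")
  if (any(ratings < 1 | ratings > 7)) stop("ratings must lie on the 1-7 scale")
  rdm(colMeans(ratings), source = "behavior")
}

#' Spearman correlation between two RDMs
#'
#' Rank correlation (average ranks for ties) over the 28 lower-triangle
#' entries, the diagonal excluded. If either RDM is constant the correlation
#' is undefined and `NA` is returned with a warning.
#'
#' @param rdm_a,rdm_b [rdm] objects (or 8x8 matrices).
#' @return Spearman's R, or `NA` if undefined.
#' @export
rdm_correlation <- function(rdm_a, rdm_b) {
  a <- rdm_vec(rdm_a)
  b <- rdm_vec(rdm_b)
  if (length(a) != length(b)) stop("RDM dimensions differ")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in an RDM; Spearman R undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' RSA time course: behavior vs time-resolved neural RDMs
#'
#' Correlates a (participant-averaged) behavioral RDM with the neural RDM at
#' every time point of one subject's pair-resolved decoding accuracies.
#' The sensory curve conventionally uses the within-hand accuracies, the
#' perceptual curve the across-hand accuracies.
#'
#' @param pair_accuracies `28 x time` matrix of hand-averaged pair accuracies
#'   (see [hand_average]).
#' @param behavior_rdm an [rdm] of ratings.
#' @return Numeric vector of Spearman R per time point.
#' @export
rsa_time_course <- function(pair_accuracies, behavior_rdm) {
  stopifnot(nrow(pair_accuracies) == 28L)
  b <- rdm_vec(behavior_rdm)
  apply(pair_accuracies, 2, function(a) {
    if (stats::sd(a) == 0) return(NA_real_)
    stats::cor(a, b, method = "spearman")
  })
}

#' Write / read an RDM as letter-labeled CSV
#' @param x an [rdm].
#' @param path file path.
#' @return `read_rdm` returns the [rdm]; `write_rdm` returns `path`
#'   invisibly.
#' @export
write_rdm <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.csv(path, row.names = 1)
  rdm(as.matrix(df))
}
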