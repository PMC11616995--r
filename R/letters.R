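#' The eight braille letters entering the main analyses
#'
#' Letters B, C, D, L, M, N, V, Z are the regular stimuli; E and O are the
#' rare catch (vigilance) letters and are excluded from all decoding.
#'
#' @return Character vector of length 8.
#' @export
braille_letters <- function() c("B", "C", "D", "L", "M", "N", "V", "Z")

#' Catch-trial letters
#' @return Character vector of length 2.
#' @export
catch_letters <- function() c("E", "O")

#' Braille 6-pin dot patterns
#'
#' Standard braille cell with dots 1-3 in the left column (top to bottom) and
#' dots 4-6 in the right column. Rows are letters, columns are dots; entries
#' are 0/1 pin states.
#'
#' @param letters which letters to return (default: the 8 regular letters).
#' @return Binary matrix `length(letters) x 6` with letter rownames.
#' @export
braille_pin_patterns <- function(letters = braille_letters()) {
  dots <- list(
    B = c(1, 2), C = c(1, 4), D = c(1, 4, 5), E = c(1, 5),
    L = c(1, 2, 3), M = c(1, 3, 4), N = c(1, 3, 4, 5), O = c(1, 3, 5),
    V = c(1, 2, 3, 6), Z = c(1, 3, 5, 6)
  )
  unknown <- setdiff(letters, names(dots))
  if (length(unknown) > 0) {
    stop("no pin pattern known for letter(s): ", paste(unknown, collapse = ", "))
  }
  m <- matrix(0L, length(letters), 6, dimnames = list(letters, paste0("dot", 1:6)))
  for (l in letters) m[l, dots[[l]]] <- 1L
  m
}

#' Latent letter dissimilarity from braille dot overlap
#'
#' Pairwise Hamming distance between the 6-pin patterns of the eight regular
#' letters. Used as the default planted geometry for the hand-independent
#' (perceptual) letter code and for synthetic similarity ratings: letters
#' sharing more pins are more similar.
#'
#' @return Symmetric 8x8 integer matrix with zero diagonal and letter dimnames.
#' @export
braille_letter_geometry <- function() {
  p <- braille_pin_patterns()
  d <- as.matrix(stats::dist(p, method = "manhattan"))
  storage.mode(d) <- "integer"
  d
}

#' Unordered letter pairs
#'
#' The 28 unordered pairs of the eight regular letters, in the canonical
#' column order of `combn(8, 2)`. All pairwise decoding results and RDM
#' vectorizations use this ordering.
#'
#' @return data.frame with columns `a`, `b` (letters) and `ia`, `ib` (indices).
#' @export
letter_pairs <- function() {
  idx <- combn(8L, 2L)
  data.frame(
    a = braille_letters()[idx[1, ]], b = braille_letters()[idx[2, ]],
    ia = idx[1, ], ib = idx[2, ],
    stringsAsFactors = FALSE
  )
}
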