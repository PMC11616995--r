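#' Epoched multichannel data
#'
#' Container for epoched trials: a `trials x channels x samples` array, a
#' strictly increasing uniform time axis in ms, a channel montage (names and
#' 3D positions), and a per-trial label table (`trial`, `kind`, `letter`,
#' `hand`). Catch trials may be carried (flagged by `kind`) but are excluded
#' from decoding.
#'
#' @param data numeric array `trials x channels x samples`.
#' @param time_ms numeric vector of sample times (ms), uniform step.
#' @param montage data.frame with `name`, `x`, `y`, `z`.
#' @param labels data.frame with one row per trial.
#' @return An object of class `braille_epochs`.
#' @export
braille_epochs <- function(data, time_ms, montage, labels) {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3] != length(time_ms)) stop("time axis length must match sample count")
  if (dim(data)[2] != nrow(montage)) stop("montage must have one row per channel")
  if (dim(data)[1] != nrow(labels)) stop("label table length must equal trial count")
  steps <- diff(time_ms)
  if (length(steps) > 0 && (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-9)) {
    stop("time axis must be strictly increasing with a uniform step")
  }
  structure(list(data = data, time_ms = time_ms, montage = montage,
                 labels = labels),
            class = "braille_epochs")
}

#' @export
print.braille_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<braille_epochs> %d trials x %d channels x %d samples (%g..%g ms)\n",
              d[1], d[2], d[3], min(x$time_ms), max(x$time_ms)))
  cat("  kinds:", paste(sprintf("%s=%d", names(table(x$labels$kind)),
                                table(x$labels$kind)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.braille_epochs <- function(x) dim(x$data)

#' Keep only regular (non-catch) trials
#' @param epochs a [braille_epochs] object.
#' @return [braille_epochs] restricted to `kind == "regular"`.
#' @export
regular_trials <- function(epochs) {
  keep <- epochs$labels$kind == "regular"
  braille_epochs(epochs$data[keep, , , drop = FALSE], epochs$time_ms,
                 epochs$montage, epochs$labels[keep, , drop = FALSE])
}

#' Write / read an epochs container
#'
#' Serializes the full container (data tensor, time axis, montage, labels) to
#' a single-file RDS-based container with a format tag, and validates on read.
#'
#' @param epochs a [braille_epochs] object.
#' @param path file path (conventionally `.epochs.rds`).
#' @return `read_epochs` returns the [braille_epochs]; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "braille_epochs"))
  saveRDS(list(format = "braillemvpa_epochs_v1",
               data = epochs$data, time_ms = epochs$time_ms,
               montage = epochs$montage, labels = epochs$labels),
          path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot parse epochs container '", path, "': ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, "braillemvpa_epochs_v1")) {
    stop("'", path, "' is not a braillemvpa epochs container")
  }
  braille_epochs(obj$data, obj$time_ms, obj$montage, obj$labels)
}
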