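#' Run code under a temporary RNG seed
#'
#' Sets the seed if one is given, restoring the caller's RNG state afterwards,
#' so seeded package functions do not disturb the session's random stream.
#'
#' @param seed integer seed or NULL (leave the RNG stream untouched).
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed; stages and
#' replicates get independent streams through this splitting scheme. The
#' result always stays below 2^31 so it is a valid R integer seed.
#'
#' @param master master seed (integer).
#' @param stream stream index (integer >= 0) or a short string tag.
#' @return Integer seed.
#' @export
split_seed <- function(master, stream) {
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  m <- 2147483647
  x <- (as.double(master) %% m)
  s <- (as.double(stream) %% m)
  as.integer(((x * 48271) %% m + (s * 69621) %% m + 1) %% m)
}
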