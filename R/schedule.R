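#' Trial schedule constructors and accessors
#'
#' A trial schedule is a data.frame with one row per trial and columns
#' `index`, `kind` (regular/catch/null), `letter`, `hand`, `onset_s`,
#' `duration_s`, `isi_s`, plus a `modality` attribute ("fmri" or "eeg").
#' Onsets are strictly increasing and satisfy
#' `onset[i+1] == onset[i] + duration[i] + isi[i]`.
#'
#' @name trial_schedule
NULL

new_trial_schedule <- function(kind, letter, hand, duration_s, isi_s, modality) {
  n <- length(kind)
  onset <- c(0, cumsum(duration_s + isi_s))[seq_len(n)]
  out <- data.frame(
    index = seq_len(n), kind = kind, letter = letter, hand = hand,
    onset_s = onset, duration_s = duration_s, isi_s = isi_s,
    stringsAsFactors = FALSE
  )
  attr(out, "modality") <- modality
  class(out) <- c("trial_schedule", "data.frame")
  out
}

balanced_conditions <- function(n_regular) {
  if (n_regular %% 16L != 0L) {
    stop("regular trial count (", n_regular, ") must be a multiple of the 16 ",
         "conditions (8 letters x 2 hands) to balance the design")
  }
  reps <- n_regular / 16L
  grid <- expand.grid(letter = braille_letters(), hand = c("left", "right"),
                      stringsAsFactors = FALSE)
  grid[rep(seq_len(16L), each = reps), , drop = FALSE]
}

#' Generate one fMRI main-experiment run schedule
#'
#' Default composition is 80 regular trials (each of the 16 letter-by-hand
#' conditions 5 times, random order), 5 catch trials and 22 null trials, for
#' 107 trials per run. Stimuli last 500 ms with a 2500-ms ISI; a null trial
#' occupies one empty 3-s slot. Catch trials are interspersed roughly every
#' `n_regular / n_catch` stimulus trials, null trials after every 3rd to 5th
#' stimulus trial (equally probable) as long as the null budget lasts; the
#' configured totals are always met exactly, the gap rules are best-effort
#' (see the `placement` attribute for the realized gaps).
#'
#' @param composition named counts `c(regular=, catch=, null=)`.
#' @param seed RNG seed (NULL: use current stream).
#' @param stim_duration_s,isi_s stimulus duration and inter-stimulus interval.
#' @return A [trial_schedule] with `modality = "fmri"`.
#' @export
generate_fmri_run_schedule <- function(composition = c(regular = 80L, catch = 5L, null = 22L),
                                       seed = NULL,
                                       stim_duration_s = 0.5, isi_s = 2.5) {
  composition <- check_composition(composition, c("regular", "catch", "null"))
  with_seed(seed, {
    conds <- balanced_conditions(composition[["regular"]])
    ord <- sample.int(nrow(conds))
    stim <- data.frame(
      kind = "regular", letter = conds$letter[ord], hand = conds$hand[ord],
      stringsAsFactors = FALSE
    )
    stim <- intersperse_catch(stim, composition[["catch"]], jitter = 2L)
    kinds <- place_nulls(stim$kind, composition[["null"]])
    letter <- rep(NA_character_, length(kinds))
    hand <- rep(NA_character_, length(kinds))
    letter[kinds != "null"] <- stim$letter
    hand[kinds != "null"] <- stim$hand
    dur <- ifelse(kinds == "null", 0, stim_duration_s)
    isi <- ifelse(kinds == "null", stim_duration_s + isi_s, isi_s)
    new_trial_schedule(kinds, letter, hand, dur, isi, modality = "fmri")
  })
}

#' Generate one EEG session schedule
#'
#' Default composition is 2720 regular trials (each of the 16 conditions 170
#' times, random order) and 541 catch trials, for 3261 trials per session.
#' Regular trials use a 500-ms ISI, catch trials a 1100-ms ISI. Catch trials
#' are separated by at least one regular trial; the gap sequence is the exact
#' mix of `floor(regular/catch)` and `floor(regular/catch)+1` regular trials
#' that sums to the regular total, in shuffled order.
#'
#' @param composition named counts `c(regular=, catch=)`.
#' @param seed RNG seed.
#' @param stim_duration_s,isi_s,catch_isi_s timing parameters (seconds).
#' @return A [trial_schedule] with `modality = "eeg"`.
#' @export
generate_eeg_session_schedule <- function(composition = c(regular = 2720L, catch = 541L),
                                          seed = NULL,
                                          stim_duration_s = 0.5, isi_s = 0.5,
                                          catch_isi_s = 1.1) {
  composition <- check_composition(composition, c("regular", "catch"))
  n_reg <- composition[["regular"]]
  n_catch <- composition[["catch"]]
  with_seed(seed, {
    conds <- balanced_conditions(n_reg)
    ord <- sample.int(nrow(conds))
    kinds <- rep("regular", n_reg)
    letter <- conds$letter[ord]
    hand <- conds$hand[ord]
    if (n_catch > 0L) {
      base <- n_reg %/% n_catch
      if (base < 1L) {
        stop("catch trials (", n_catch, ") cannot each be separated by at ",
             "least one regular trial given ", n_reg, " regular trials")
      }
      n_long <- n_reg - base * n_catch
      gaps <- sample(c(rep(base + 1L, n_long), rep(base, n_catch - n_long)))
      kinds <- character(0)
      letter2 <- character(0)
      hand2 <- character(0)
      pos <- 0L
      for (g in gaps) {
        take <- seq_len(g) + pos
        kinds <- c(kinds, rep("regular", g), "catch")
        letter2 <- c(letter2, letter[take], sample(catch_letters(), 1L))
        hand2 <- c(hand2, hand[take], sample(c("left", "right"), 1L))
        pos <- pos + g
      }
      letter <- letter2
      hand <- hand2
    }
    isi <- ifelse(kinds == "catch", catch_isi_s, isi_s)
    new_trial_schedule(kinds, letter, hand, stim_duration_s, isi, modality = "eeg")
  })
}

check_composition <- function(composition, fields) {
  if (is.null(names(composition))) names(composition) <- fields[seq_along(composition)]
  missing <- setdiff(fields, names(composition))
  comp <- stats::setNames(integer(length(fields)), fields)
  comp[names(composition)] <- as.integer(composition)
  if (any(comp < 0L)) stop("composition counts must be non-negative")
  comp
}

# Insert n_catch catch trials into the regular sequence, spaced roughly evenly
# (every n_regular/n_catch regular trials, uniform jitter of +/- `jitter`).
intersperse_catch <- function(stim, n_catch, jitter = 2L) {
  if (n_catch == 0L) return(stim)
  n_reg <- nrow(stim)
  step <- n_reg / n_catch
  after <- round(step * seq_len(n_catch) - step / 2) +
    sample(seq.int(-jitter, jitter), n_catch, replace = TRUE)
  after <- sort(pmin(pmax(after, 1L), n_reg))
  catch <- data.frame(
    kind = "catch",
    letter = sample(catch_letters(), n_catch, replace = TRUE),
    hand = sample(c("left", "right"), n_catch, replace = TRUE),
    stringsAsFactors = FALSE
  )
  pieces <- list()
  prev <- 0L
  for (i in seq_len(n_catch)) {
    if (after[i] > prev) {
      pieces[[length(pieces) + 1L]] <- stim[(prev + 1L):after[i], , drop = FALSE]
      prev <- after[i]
    }
    pieces[[length(pieces) + 1L]] <- catch[i, , drop = FALSE]
  }
  if (prev < n_reg) pieces[[length(pieces) + 1L]] <- stim[(prev + 1L):n_reg, , drop = FALSE]
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Distribute n_null null slots among the stimulus trials: after every 3rd-5th
# stimulus trial (equally probable) while the budget lasts; any remainder goes
# to random positions so the printed total is met exactly.
place_nulls <- function(stim_kinds, n_null) {
  n_stim <- length(stim_kinds)
  if (n_null == 0L) return(stim_kinds)
  null_after <- integer(0)
  pos <- 0L
  while (length(null_after) < n_null) {
    pos <- pos + sample(3:5, 1L)
    if (pos >= n_stim) break
    null_after <- c(null_after, pos)
  }
  if (length(null_after) < n_null) {
    extra <- setdiff(seq_len(n_stim - 1L), null_after)
    need <- n_null - length(null_after)
    if (need > length(extra)) stop("too many null trials for this run length")
    null_after <- c(null_after, extra[sample.int(length(extra), need)])
  }
  out <- character(n_stim + n_null)
  is_null <- logical(n_stim + n_null)
  shift <- cumsum(tabulate(null_after, nbins = n_stim))
  stim_pos <- seq_len(n_stim) + c(0L, shift[-n_stim])
  out[stim_pos] <- stim_kinds
  out[out == ""] <- "null"
  out
}

#' Duration of one localizer stimulation block
#'
#' A localizer block presents `n_stim` letters back to back, each shown for
#' `on_ms` followed by `off_ms` of blank. Defaults give 18 x (500 + 300) ms =
#' 14.4 s.
#'
#' @param n_stim number of letter presentations per block.
#' @param on_ms,off_ms presentation and blank durations (ms).
#' @return Block duration in seconds.
#' @export
localizer_block_duration <- function(n_stim = 18L, on_ms = 500, off_ms = 300) {
  n_stim * (on_ms + off_ms) / 1000
}

#' Tabulate a schedule's composition
#' @param schedule a [trial_schedule].
#' @return Named integer vector of per-kind counts.
#' @export
schedule_composition <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  tab <- table(factor(schedule$kind, levels = c("regular", "catch", "null")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Write / read a trial schedule as TSV
#'
#' Columns: index, kind, letter, hand, onset_s, duration_s, isi_s. The
#' modality is kept in a `# modality:` header comment.
#'
#' @param schedule a [trial_schedule].
#' @param path file path.
#' @return `read_schedule` returns the [trial_schedule]; `write_schedule`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# modality: ", attr(schedule, "modality")), con)
  write.table(as.data.frame(schedule), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  first <- readLines(path, n = 1L)
  modality <- sub("^# modality:\\s*", "", first)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$letter <- as.character(df$letter)
  df$hand <- as.character(df$hand)
  attr(df, "modality") <- modality
  class(df) <- c("trial_schedule", "data.frame")
  df
}
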