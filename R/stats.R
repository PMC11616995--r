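.wsr_cache <- new.env(parent = emptyenv())

# Exact null distribution of the signed-rank sum over the given rank values
# (doubled to integers so average ranks from ties stay exact). Returns the
# probability vector over the support 0..sum(ranks2) in half-rank units.
wsr_exact_dist <- function(ranks2) {
  key <- paste(sort(ranks2), collapse = ",")
  hit <- .wsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  total <- sum(ranks2)
  prob <- numeric(total + 1)
  prob[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), prob[seq_len(total + 1 - r)])
    prob <- 0.5 * (prob + shifted)
  }
  .wsr_cache[[key]] <- prob
  prob
}

#' Wilcoxon signed-rank test against a location
#'
#' One-sample signed-rank test of H0: the distribution of `values` is
#' symmetric about `mu`. Zeros are handled by the Pratt method (ranked with
#' the rest, then discarded); ties get average ranks. The p-value is exact
#' (full null distribution of the rank sum, valid with ties) for up to 25
#' nonzero differences and a normal approximation with continuity correction
#' above.
#'
#' @param values numeric vector (n >= 5 recommended for any power).
#' @param mu null location (e.g. 50 for % decoding accuracy, 0 for
#'   correlations or difference scores).
#' @param tail `"greater"` (H1: location > mu, the usual above-chance test)
#'   or `"two_sided"`.
#' @param exact_max largest nonzero-difference count for which the exact
#'   distribution is used.
#' @return The p-value. `NA` (with a warning) if every value equals `mu`.
#' @export
wilcoxon_signed_rank <- function(values, mu = 0,
                                 tail = c("greater", "two_sided"),
                                 exact_max = 25L) {
  tail <- match.arg(tail)
  d <- values[!is.na(values)] - mu
  if (length(d) == 0 || all(d == 0)) {
    warning("all values equal mu; signed-rank test degenerate")
    return(NA_real_)
  }
  r <- rank(abs(d))        # zeros ranked too (Pratt) ...
  keep <- d != 0           # ... then discarded
  r <- r[keep]
  d <- d[keep]
  w <- sum(r[d > 0])
  n <- length(d)
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    dist <- wsr_exact_dist(r2)
    w2 <- round(2 * w)
    support <- seq_along(dist) - 1L
    p_greater <- sum(dist[support >= w2 - 1e-9])
    p_less <- sum(dist[support <= w2 + 1e-9])
  } else {
    mu_w <- sum(r) / 2
    sd_w <- sqrt(sum(r^2) / 4)
    p_greater <- stats::pnorm(w - 0.5, mu_w, sd_w, lower.tail = FALSE)
    p_less <- stats::pnorm(w + 0.5, mu_w, sd_w)
  }
  if (tail == "greater") p_greater else min(1, 2 * min(p_greater, p_less))
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up false-discovery-rate control at level `q`; returns which
#' hypotheses are rejected.
#'
#' @param pvals p-values, finite in (0, 1].
#' @param q FDR level.
#' @return Logical vector of rejections.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must be finite and in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Group significance trace of a time course matrix
#'
#' Per time point, a Wilcoxon signed-rank test of the subjects' values
#' against `mu`, followed by Benjamini-Hochberg FDR correction across time
#' points. Time points with a degenerate test (all values at `mu`) are
#' treated as non-significant.
#'
#' @param timecourses `subjects x time` matrix.
#' @param time_ms time axis.
#' @param mu chance/null level tested against.
#' @param tail test tail (see [wilcoxon_signed_rank]).
#' @param q FDR level.
#' @return data.frame with columns `time_ms`, `p`, `sig`.
#' @export
significance_trace <- function(timecourses, time_ms, mu = 50,
                               tail = "greater", q = 0.05) {
  stopifnot(ncol(timecourses) == length(time_ms))
  p <- vapply(seq_len(ncol(timecourses)), function(i) {
    suppressWarnings(wilcoxon_signed_rank(timecourses[, i], mu = mu, tail = tail))
  }, numeric(1))
  sig <- rep(FALSE, length(p))
  ok <- !is.na(p)
  if (any(ok)) sig[ok] <- fdr_bh(p[ok], q = q)
  data.frame(time_ms = time_ms, p = p, sig = sig)
}

#' Onset latency of a significance trace
#'
#' The earliest post-stimulus time point starting a run of `k` consecutive
#' FDR-significant time points (the run must lie entirely at `t >= 0`).
#'
#' @param trace data.frame from [significance_trace] (needs `time_ms`,
#'   `sig`).
#' @param k required run length in time points.
#' @return Onset time in ms, or `NA` if no such run exists.
#' @export
onset_latency <- function(trace, k = 50) {
  if (k < 1) stop("k must be at least 1")
  post <- trace[trace$time_ms >= 0, , drop = FALSE]
  sig <- post$sig
  n <- length(sig)
  if (n < k) return(NA_real_)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (sig[i]) run + 1L else 0L
    if (run == k) return(post$time_ms[i - k + 1L])
  }
  NA_real_
}

#' Bootstrap confidence interval for a group onset latency
#'
#' Resamples the subject pool with replacement `n_boot` times; for each
#' resample recomputes the full group trace (signed-rank tests + FDR) and its
#' onset latency, and reports the 95% percentile interval over the defined
#' onsets (the fraction of resamples without an onset is reported alongside).
#'
#' @inheritParams significance_trace
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @param k consecutive-significance criterion (see [onset_latency]).
#' @param conf confidence level of the percentile interval.
#' @return A `latency_estimate`: list with `onset` (full-sample), `ci_low`,
#'   `ci_high`, `n_boot`, `k`, `prop_undefined`, and the resampled onsets.
#' @export
bootstrap_onset_ci <- function(timecourses, time_ms, mu = 50,
                               tail = "greater", q = 0.05,
                               n_boot = 1000, seed = NULL, k = 50,
                               conf = 0.95) {
  n_sub <- nrow(timecourses)
  if (n_sub < 2) stop("need at least 2 subjects")
  onset_full <- onset_latency(
    significance_trace(timecourses, time_ms, mu = mu, tail = tail, q = q), k = k)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_sub, replace = TRUE)
      onset_latency(
        significance_trace(timecourses[idx, , drop = FALSE], time_ms,
                           mu = mu, tail = tail, q = q), k = k)
    }, numeric(1))
  })
  defined <- boots[!is.na(boots)]
  if (length(defined) == 0) {
    ci <- c(NA_real_, NA_real_)
    warning("no bootstrap resample produced a defined onset")
  } else {
    a <- (1 - conf) / 2
    ci <- unname(quantile(defined, c(a, 1 - a)))
  }
  structure(list(onset = onset_full, ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, k = k,
                 prop_undefined = mean(is.na(boots)), boot_onsets = boots),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> onset %s ms (%s-%s ms, %d bootstraps, %.0f%% undefined)\n",
              format(x$onset), format(x$ci_low), format(x$ci_high),
              x$n_boot, 100 * x$prop_undefined))
  invisible(x)
}

#' Bootstrap test of an onset-latency difference
#'
#' Paired bootstrap over the common subject pool: each resample recomputes
#' both group traces and their onsets; the statistic is
#' `onset(b) - onset(a)`. The one-tailed p-value (H1: condition b emerges
#' later than condition a) is the proportion of resampled differences less
#' than or equal to zero. Resamples where either onset is undefined are
#' excluded and counted.
#'
#' @param tc_a,tc_b `subjects x time` matrices for the two conditions, same
#'   subject order.
#' @inheritParams bootstrap_onset_ci
#' @param mu_a,mu_b null levels for the two traces (both 50 for % accuracy;
#'   use 0 for difference scores or correlations).
#' @return List with `diff_ms` (full-sample difference), `ci_low`,
#'   `ci_high`, `p`, `prop_undefined`, `boot_diffs`.
#' @export
bootstrap_latency_difference <- function(tc_a, tc_b, time_ms,
                                         mu_a = 50, mu_b = 50,
                                         tail = "greater", q = 0.05,
                                         n_boot = 1000, seed = NULL, k = 50,
                                         conf = 0.95) {
  stopifnot(nrow(tc_a) == nrow(tc_b), ncol(tc_a) == ncol(tc_b))
  n_sub <- nrow(tc_a)
  onset_a <- onset_latency(
    significance_trace(tc_a, time_ms, mu = mu_a, tail = tail, q = q), k = k)
  onset_b <- onset_latency(
    significance_trace(tc_b, time_ms, mu = mu_b, tail = tail, q = q), k = k)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_sub, replace = TRUE)
      oa <- onset_latency(
        significance_trace(tc_a[idx, , drop = FALSE], time_ms, mu = mu_a,
                           tail = tail, q = q), k = k)
      ob <- onset_latency(
        significance_trace(tc_b[idx, , drop = FALSE], time_ms, mu = mu_b,
                           tail = tail, q = q), k = k)
      ob - oa
    }, numeric(1))
  })
  defined <- diffs[!is.na(diffs)]
  if (length(defined) == 0) {
    warning("no bootstrap resample produced both onsets")
    return(list(diff_ms = onset_b - onset_a, ci_low = NA_real_,
                ci_high = NA_real_, p = NA_real_, prop_undefined = 1,
                boot_diffs = diffs))
  }
  a <- (1 - conf) / 2
  ci <- unname(quantile(defined, c(a, 1 - a)))
  list(diff_ms = onset_b - onset_a, ci_low = ci[1], ci_high = ci[2],
       p = mean(defined <= 0), prop_undefined = mean(is.na(diffs)),
       boot_diffs = diffs)
}
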