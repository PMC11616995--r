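test_that("exact signed-rank p matches full sign-pattern enumeration", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    vals <- round(rnorm(n, mean = 0.3), 1)  # rounding induces ties and zeros
    if (all(vals == 0)) vals[1] <- 0.5
    for (tail in c("greater", "two_sided")) {
      expect_equal(wilcoxon_signed_rank(vals, mu = 0, tail = tail),
                   wsr_enumerate(vals, 0, tail), tolerance = 1e-12)
    }
  }
})

test_that("signed-rank edge cases have their closed-form p-values", {
  # n = 11, all values above mu: one-tailed p = 2^-11
  set.seed(42)
  vals <- 50 + runif(11, 0.5, 5)
  expect_equal(wilcoxon_signed_rank(vals, mu = 50), 1 / 2^11)
  # symmetric values around mu: p close to 0.5
  sym <- 50 + c(-4, -3, -2, -1, 1, 2, 3, 4) + 0.001 * rnorm(8)
  expect_lt(abs(wilcoxon_signed_rank(sym, mu = 50) - 0.5), 0.2)
  # degenerate: everything at mu
  expect_warning(p <- wilcoxon_signed_rank(rep(50, 6), mu = 50), "degenerate")
  expect_true(is.na(p))
})

test_that("exact signed-rank p matches wilcox.test when ties are absent", {
  set.seed(43)
  for (i in 1:10) {
    vals <- rnorm(10)
    expect_equal(wilcoxon_signed_rank(vals, mu = 0, tail = "greater"),
                 wilcox.test(vals, mu = 0, alternative = "greater",
                             exact = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(wilcoxon_signed_rank(vals, mu = 0, tail = "two_sided"),
                 wilcox.test(vals, mu = 0, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("the normal approximation is close to exact near the boundary", {
  set.seed(44)
  vals <- rnorm(26, 0.3)
  p_apx <- wilcoxon_signed_rank(vals, mu = 0)                 # n = 26: approx
  p_ex <- wilcoxon_signed_rank(vals, mu = 0, exact_max = 30)  # forced exact
  expect_lt(abs(p_apx - p_ex), 0.01)
})

test_that("BH decisions match a brute-force step-up rule on random vectors", {
  step_up <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    passed <- which(p[ord] <= q * seq_len(m) / m)
    rej <- logical(m)
    if (length(passed) > 0) rej[ord[seq_len(max(passed))]] <- TRUE
    rej
  }
  set.seed(45)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(c(1, 2, 3), 1)
    expect_identical(fdr_bh(p, q = 0.05), step_up(p, 0.05))
  }
})

test_that("BH handles the printed examples and degenerate inputs", {
  expect_identical(fdr_bh(0.04, q = 0.05), TRUE)   # m = 1: raw threshold
  # step-up by hand: thresholds i*q/m = .0125, .025, .0375, .05; 0.04
  # exceeds its threshold, so exactly the first two are rejected
  expect_identical(fdr_bh(c(0.01, 0.02, 0.04, 0.9), q = 0.05),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(fdr_bh(rep(1, 5), q = 0.05), rep(FALSE, 5))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, NA)), "finite")
  expect_error(fdr_bh(c(0.5, 0)), "finite|\\(0, 1\\]")
})

test_that("onset latency follows the consecutive-significance criterion", {
  time_ms <- seq(-100, 999)
  sig <- time_ms >= 62
  trace <- data.frame(time_ms = time_ms, p = ifelse(sig, 0.001, 0.5), sig = sig)
  expect_equal(onset_latency(trace, k = 50), 62)
  # a 49-point island does not qualify for k = 50
  sig2 <- time_ms >= 100 & time_ms <= 148
  trace2 <- data.frame(time_ms = time_ms, p = 0.5, sig = sig2)
  expect_true(is.na(onset_latency(trace2, k = 50)))
  expect_equal(onset_latency(trace2, k = 49), 100)
  # prestimulus significance never counts
  sig3 <- time_ms < 0
  expect_true(is.na(onset_latency(data.frame(time_ms = time_ms, sig = sig3),
                                  k = 10)))
  expect_error(onset_latency(trace, k = 0), "at least 1")
})

test_that("onset detection equals a brute-force sliding-window scan", {
  scan_onset <- function(sig, time_ms, k) {
    post <- which(time_ms >= 0)
    for (i in post) {
      if (i + k - 1 <= length(sig) && all(sig[i:(i + k - 1)])) {
        return(time_ms[i])
      }
    }
    NA_real_
  }
  set.seed(46)
  time_ms <- seq(-20, 79)
  for (i in 1:200) {
    sig <- runif(100) < 0.6
    trace <- data.frame(time_ms = time_ms, sig = sig)
    k <- sample(1:10, 1)
    expect_identical(onset_latency(trace, k = k),
                     scan_onset(sig, time_ms, k))
  }
})

test_that("group traces combine signed-rank tests with FDR", {
  set.seed(47)
  tc <- matrix(50 + rnorm(8 * 20, 0), 8, 20)
  tc[, 11:20] <- tc[, 11:20] + 10   # strong effect in the second half
  tr <- significance_trace(tc, time_ms = seq_len(20) * 10 - 10, mu = 50)
  expect_true(all(tr$sig[11:20]))
  expect_true(mean(tr$sig[1:10]) <= 0.2)
  expect_identical(nrow(tr), 20L)
})

test_that("bootstrap onset CI collapses with zero between-subject variation", {
  time_ms <- seq(-50, 149, by = 10)
  curve <- ifelse(time_ms >= 40, 95, 50)
  tc <- matrix(rep(curve, each = 6), 6)  # all subjects identical
  est <- bootstrap_onset_ci(tc, time_ms, mu = 50, n_boot = 100, seed = 1, k = 3)
  expect_equal(est$onset, 40)
  expect_equal(est$ci_low, 40)
  expect_equal(est$ci_high, 40)
  expect_equal(est$prop_undefined, 0)
})

test_that("bootstrap onset CI is deterministic under a fixed seed", {
  set.seed(48)
  tc <- matrix(50 + rnorm(6 * 20) + rep(ifelse(seq_len(20) > 8, 6, 0),
                                        each = 6), 6)
  time_ms <- seq_len(20) * 10 - 50
  e1 <- bootstrap_onset_ci(tc, time_ms, n_boot = 50, seed = 7, k = 2)
  e2 <- bootstrap_onset_ci(tc, time_ms, n_boot = 50, seed = 7, k = 2)
  expect_identical(e1$boot_onsets, e2$boot_onsets)
  expect_error(bootstrap_onset_ci(tc[1, , drop = FALSE], time_ms),
               "at least 2")
})

test_that("latency difference of identical conditions is null", {
  time_ms <- seq(-50, 149, by = 10)
  set.seed(49)
  curve <- ifelse(time_ms >= 30, 90, 50)
  tc <- matrix(rep(curve, each = 8), 8) + matrix(rnorm(8 * 20, sd = 0.5), 8)
  res <- bootstrap_latency_difference(tc, tc, time_ms, n_boot = 100,
                                      seed = 2, k = 3)
  expect_equal(res$diff_ms, 0)
  # every resampled difference is 0, all counted as <= 0
  expect_equal(res$p, 1)
  # swapping the conditions mirrors the difference distribution
  res_ab <- bootstrap_latency_difference(tc, tc + 0, time_ms, n_boot = 50,
                                         seed = 3, k = 3)
  expect_equal(res_ab$boot_diffs, -res_ab$boot_diffs)
})

test_that("a planted latency gap is detected by the paired bootstrap", {
  time_ms <- seq(-50, 249, by = 10)
  set.seed(50)
  mk <- function(onset) {
    curve <- ifelse(time_ms >= onset, 85, 50)
    matrix(rep(curve, each = 9), 9) + matrix(rnorm(9 * length(time_ms)), 9)
  }
  res <- bootstrap_latency_difference(mk(30), mk(130), time_ms,
                                      n_boot = 200, seed = 4, k = 3)
  expect_gt(res$diff_ms, 50)
  expect_lt(res$p, 0.05)
})

test_that("null time courses rarely produce any onset", {
  # type-I control of the onset criterion itself, across replicates
  set.seed(51)
  n_rep <- 40
  hits <- vapply(seq_len(n_rep), function(r) {
    tc <- matrix(50 + rnorm(10 * 30), 10, 30)
    tr <- significance_trace(tc, time_ms = seq(0, 290, by = 10), mu = 50)
    !is.na(onset_latency(tr, k = 5))
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})
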