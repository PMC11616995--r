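# Shared fixture builders; everything is generated in code at test time.

# Minimal epochs object: n_per_cond regular trials for each of the 16
# conditions, iid N(0, 1) channels, no planted signal unless `signal` is a
# function(cond) returning a channel pattern added from sample `on_from`.
tiny_epochs <- function(n_per_cond = 4, n_channels = 6, n_samples = 10,
                        srate = 100, signal = NULL, on_from = 1,
                        seed = 1) {
  ct <- condition_table()
  labels <- data.frame(
    trial = seq_len(16 * n_per_cond),
    kind = "regular",
    letter = rep(ct$letter, each = n_per_cond),
    hand = rep(ct$hand, each = n_per_cond),
    stringsAsFactors = FALSE
  )
  step <- 1000 / srate
  time_ms <- seq(0, by = step, length.out = n_samples)
  set.seed(seed)
  data <- array(rnorm(nrow(labels) * n_channels * n_samples),
                dim = c(nrow(labels), n_channels, n_samples))
  if (!is.null(signal)) {
    for (tr in seq_len(nrow(labels))) {
      cc <- condition_index(labels$letter[tr], labels$hand[tr])
      pat <- signal(cc)
      for (s in on_from:n_samples) data[tr, , s] <- data[tr, , s] + pat
    }
  }
  braille_epochs(data, time_ms, synthetic_montage(n_channels), labels)
}

# Pseudo-trial array (16 x 5 x features) with condition means `mu` (16 x f)
# plus iid noise; the raw ingredient of the decoding engine.
tiny_pseudo <- function(mu, noise_sd = 1, seed = 1) {
  f <- ncol(mu)
  set.seed(seed)
  out <- array(rnorm(16 * 5 * f, sd = noise_sd), dim = c(16, 5, f))
  for (cc in 1:16) out[cc, , ] <- out[cc, , ] + matrix(mu[cc, ], 5, f, byrow = TRUE)
  out
}

# Condition mean builder: hand-specific patterns (sensory-like) and/or
# letter-shared patterns (perceptual-like), drawn once per seed.
condition_means <- function(n_features, sensory = 0, perceptual = 0, seed = 1) {
  set.seed(seed)
  P <- matrix(rnorm(16 * n_features), 16, n_features)
  Q <- matrix(rnorm(8 * n_features), 8, n_features)
  ct <- condition_table()
  sensory * P + perceptual * Q[match(ct$letter, braille_letters()), , drop = FALSE]
}

# Brute-force oracle: exact signed-rank p by enumerating all 2^n sign
# patterns over the nonzero differences (Pratt zero handling as in the
# implementation under test, but the distribution comes from enumeration).
wsr_enumerate <- function(values, mu, tail = "greater") {
  d <- values - mu
  r_all <- rank(abs(d))
  keep <- d != 0
  r <- r_all[keep]
  w_obs <- sum(r[d[keep] > 0])
  n <- length(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- as.vector(signs %*% r)
  p_greater <- mean(w_null >= w_obs - 1e-9)
  p_less <- mean(w_null <= w_obs + 1e-9)
  if (tail == "greater") p_greater else min(1, 2 * min(p_greater, p_less))
}
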