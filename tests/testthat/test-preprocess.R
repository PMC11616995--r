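test_that("baseline correction zeroes the prestimulus mean", {
  ep <- tiny_epochs(n_per_cond = 2, n_channels = 4, n_samples = 20, seed = 2)
  ep$time_ms <- seq(-100, 90, by = 10)
  bc <- baseline_correct(ep)
  base <- apply(bc$data[, , bc$time_ms <= 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-10)
})

test_that("baseline correction handles constant and offset epochs exactly", {
  ep <- tiny_epochs(n_per_cond = 1, n_channels = 3, n_samples = 10, seed = 1)
  ep$time_ms <- seq(-50, 40, by = 10)
  ep$data[] <- 7
  expect_true(all(baseline_correct(ep)$data == 0))
  # adding 3.0 to one channel's prestim and epoch shifts it back by -3.0
  ep2 <- tiny_epochs(n_per_cond = 1, n_channels = 3, n_samples = 10, seed = 1)
  ep2$time_ms <- seq(-50, 40, by = 10)
  shifted <- ep2
  shifted$data[, 2, ] <- shifted$data[, 2, ] + 3
  expect_equal(baseline_correct(shifted)$data, baseline_correct(ep2)$data)
  expect_error(baseline_correct(ep2, window_ms = c(-500, -400)), "no samples")
})

test_that("noise normalization whitens a planted covariance", {
  set.seed(5)
  n_ch <- 5
  A <- matrix(rnorm(n_ch^2), n_ch)
  sigma0 <- crossprod(A) + diag(n_ch)
  cf <- chol(sigma0)
  ep <- tiny_epochs(n_per_cond = 60, n_channels = n_ch, n_samples = 6, seed = 6)
  for (s in seq_len(dim(ep$data)[3])) ep$data[, , s] <- ep$data[, , s] %*% cf
  wh <- noise_normalize(ep, return_matrix = TRUE)
  # empirical covariance of whitened single-sample patterns ~ identity
  x <- wh$data[, , 1]
  emp <- cov(x)
  expect_lt(norm(emp - diag(n_ch), "F") / n_ch, 0.15)
  # and the whitener agrees with the closed-form inverse square root of the
  # pooled covariance estimate
  sg <- attr(wh, "sigma")
  e <- eigen(sg, symmetric = TRUE)
  w_ref <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  expect_equal(attr(wh, "whitener"), w_ref, tolerance = 1e-10)
})

test_that("noise normalization is near-identity for already-white data", {
  ep <- tiny_epochs(n_per_cond = 80, n_channels = 4, n_samples = 5, seed = 7)
  wh <- noise_normalize(ep, return_matrix = TRUE)
  w <- attr(wh, "whitener")
  scale <- mean(diag(w))
  expect_lt(max(abs(w / scale - diag(4))), 0.1)
})

test_that("2x2 whitening matches the analytic inverse square root", {
  # closed form for sigma = [[a, c], [c, b]]: sigma^(-1/2) =
  # (sigma + sqrt(det) I) / (sqrt(det) * sqrt(a + b + 2 sqrt(det)))^... via
  # the identity inv_sqrt = inv(sqrtm); sqrtm(2x2) = (sigma + s I)/t with
  # s = sqrt(det), t = sqrt(trace + 2 s)
  sigma <- matrix(c(2, 0.6, 0.6, 1), 2)
  s <- sqrt(det(sigma))
  t <- sqrt(sum(diag(sigma)) + 2 * s)
  sqrtm <- (sigma + s * diag(2)) / t
  expect_equal(matrix_inv_sqrt(sigma), solve(sqrtm), tolerance = 1e-12)
})

test_that("whitening twice with the frozen covariance applies its inverse", {
  set.seed(8)
  A <- matrix(rnorm(9), 3)
  sigma <- crossprod(A) + diag(3)
  w <- matrix_inv_sqrt(sigma)
  expect_equal(w %*% w, solve(sigma), tolerance = 1e-10)
  expect_equal(w %*% sigma %*% w, diag(3), tolerance = 1e-10)
})

test_that("singular covariance without shrinkage is rejected", {
  ep <- tiny_epochs(n_per_cond = 2, n_channels = 6, n_samples = 3, seed = 9)
  ep$data[, 2, ] <- ep$data[, 1, ]  # duplicated channel: exactly singular
  expect_error(noise_normalize(ep, shrinkage = 0), "singular")
  expect_error(noise_normalize(ep, shrinkage = 2), "between|\\[0, 1\\]")
  # with a positive shrinkage intensity the duplicated channel is tolerated
  expect_s3_class(noise_normalize(ep, shrinkage = 0.2), "braille_epochs")
})

test_that("pseudo-trial binning reproduces the printed counts", {
  x <- matrix(rnorm(170 * 3), 170, 3)
  pt <- bin_pseudotrials(x, 34, seed = 1)
  expect_identical(nrow(pt), 5L)          # 170 trials, bin 34 -> 5
  pt2 <- bin_pseudotrials(matrix(rnorm(340 * 2), 340, 2), 68, seed = 1)
  expect_identical(nrow(pt2), 5L)         # 340 trials, bin 68 -> 5
  one <- bin_pseudotrials(x[1:34, ], 34, seed = 1)
  expect_identical(nrow(one), 1L)         # n = bin -> single grand mean
  expect_equal(as.vector(one), colMeans(x[1:34, ]))
  expect_error(bin_pseudotrials(x, 0), "at least 1")
  expect_error(bin_pseudotrials(x[1:3, ], 10), "at least bin_size")
})

test_that("binning is a disjoint partition and means are auditable", {
  x <- matrix(rnorm(37 * 4), 37, 4)
  pt <- bin_pseudotrials(x, 7, seed = 3)
  members <- attr(pt, "members")
  expect_identical(length(members), 5L)   # floor(37/7); 2 leftovers dropped
  all_used <- unlist(members)
  expect_identical(anyDuplicated(all_used), 0L)
  expect_true(all(lengths(members) == 7L))
  for (i in seq_along(members)) {
    expect_equal(pt[i, ], colMeans(x[members[[i]], ]))
  }
})

test_that("pseudo-run binning always yields five pseudo-runs", {
  arr <- array(rnorm(10 * 16 * 3), c(10, 16, 3))
  pr <- bin_pseudoruns(arr, seed = 1)
  expect_identical(dim(pr), c(16L, 5L, 3L))       # 10 runs -> bins of 2
  expect_true(all(lengths(attr(pr, "members")) == 2L))
  arr25 <- array(rnorm(25 * 16 * 2), c(25, 16, 2))
  pr25 <- bin_pseudoruns(arr25, seed = 1)
  expect_true(all(lengths(attr(pr25, "members")) == 5L))  # 25 runs -> bins of 5
  # 5 runs: singleton pseudo-runs identical to the runs themselves
  arr5 <- array(rnorm(5 * 16 * 2), c(5, 16, 2))
  pr5 <- bin_pseudoruns(arr5, seed = 2)
  ord <- unlist(attr(pr5, "members"))
  for (p in 1:5) expect_equal(pr5[, p, ], arr5[ord[p], , ])
  expect_error(bin_pseudoruns(array(rnorm(4 * 16 * 2), c(4, 16, 2))),
               "at least 5")
})
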