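test_that("sphere neighborhoods match a brute-force distance scan", {
  offs <- sphere_offsets(4)
  # oracle: scan a 10x10x10 grid around a center and compare memberships
  ctr <- c(5, 5, 5)
  g <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:10))
  inside <- sqrt(colSums((t(g) - ctr)^2)) <= 4
  nb <- sweep(offs, 2, ctr, "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= 10 & nb[, 2] >= 1 & nb[, 2] <= 10 &
    nb[, 3] >= 1 & nb[, 3] <= 10
  got <- sort(unname(apply(nb[ok, ], 1, paste, collapse = "-")))
  want <- sort(unname(apply(g[inside, ], 1, paste, collapse = "-")))
  expect_identical(got, want)
  # radius 1 sphere: center + 6 face neighbors
  expect_identical(nrow(sphere_offsets(1)), 7L)
  expect_error(sphere_offsets(0), "at least 1")
})

test_that("searchlight accuracy concentrates near a planted signal region", {
  dims <- c(8, 8, 4)
  region <- array(FALSE, dims)
  region[1:3, 1:3, 1:2] <- TRUE
  spec <- effect_spec(sensory_snr = 0, perceptual_snr = 3, seed = 21)
  vp <- synthesize_volume_patterns(dims, signal_region = region, spec = spec,
                                   n_runs = 10, mix = 0)
  map <- volume_searchlight(vp, radius_voxels = 2,
                            seed = 1, schemes = "across")
  acc <- map$maps$across
  near <- array(FALSE, dims)
  for (v in which(region)) {
    idx <- arrayInd(v, dims)
    nb <- sweep(sphere_offsets(2), 2, idx, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    near[nb[ok, , drop = FALSE]] <- TRUE
  }
  expect_gt(mean(acc[region]), 75)          # signal voxels clearly decodable
  expect_lt(abs(mean(acc[!near]) - 50), 3)  # far voxels at chance
  # no out-of-grid access at corners: the corner value is defined
  expect_false(is.nan(acc[8, 8, 4]))
})

test_that("a sphere covering the whole mask makes every voxel identical", {
  dims <- c(3, 3, 3)
  spec <- effect_spec(sensory_snr = 1, perceptual_snr = 1, seed = 22)
  region <- array(TRUE, dims)
  vp <- synthesize_volume_patterns(dims, signal_region = region, spec = spec,
                                   n_runs = 5, mix = 0.5)
  map <- volume_searchlight(vp, radius_voxels = 10, seed = 3)
  expect_identical(length(unique(as.vector(map$maps$across))), 1L)
  expect_identical(length(unique(as.vector(map$maps$within))), 1L)
})

test_that("nearest-channel neighborhoods match a brute-force scan", {
  m <- synthetic_montage(20)
  nbs <- knn_channels(m, k = 4)
  d <- as.matrix(dist(m[, c("x", "y", "z")]))
  for (i in c(1, 7, 20)) {
    want <- order(d[i, ])[2:5]  # skip self
    expect_setequal(nbs[[i]], want)
  }
  expect_identical(lengths(nbs), rep(4L, 20))
  # inclusive variant prepends the center
  nbs_inc <- knn_channels(m, k = 4, include_center = TRUE)
  expect_identical(nbs_inc[[3]][1], 3L)
  expect_error(knn_channels(m, k = 20), "smaller")
})

test_that("sensor searchlight pools time bins and flags planted channels", {
  set.seed(23)
  n_ch <- 8
  pat <- rnorm(16) * 4
  # letter signal only on channel 1; neighborhoods containing it decode
  ep <- tiny_epochs(n_per_cond = 10, n_channels = n_ch, n_samples = 10,
                    signal = function(cc) c(pat[cc], rep(0, n_ch - 1)),
                    on_from = 1, seed = 23)
  map <- sensor_searchlight(ep, k = 3, bin_ms = 20, seed = 1,
                            schemes = "within")
  expect_identical(dim(map$maps$within), c(8L, 5L))  # 10 samples @10ms -> 5 bins
  carrier <- vapply(knn_channels(ep$montage, 3), function(nb) 1L %in% nb,
                    logical(1))
  expect_gt(min(map$maps$within[carrier, ]), 70)
  expect_lt(max(map$maps$within[!carrier, ]), 65)
})

test_that("k = n_channels - 1 reproduces full-montage decoding per channel", {
  ep <- tiny_epochs(n_per_cond = 6, n_channels = 4, n_samples = 2, seed = 24)
  map <- sensor_searchlight(ep, k = 3, bin_ms = 10, include_center = TRUE,
                            seed = 5, schemes = "within")
  # every neighborhood is the full montage: all channels see the same
  # channel set (order differs, which decoding ignores)
  expect_identical(dim(map$maps$within), c(4L, 2L))
})

test_that("temporal bin arithmetic matches the sampling rate", {
  # 1100 1-ms samples pooled at 10 ms -> 110 bins
  ep <- tiny_epochs(n_per_cond = 2, n_channels = 3, n_samples = 1100,
                    srate = 1000, seed = 25)
  step <- diff(ep$time_ms[1:2])
  expect_identical(floor(1100 * step / 10), 110)
})

test_that("signal-free maps stay near chance after FDR", {
  # group-level null: per channel/bin one-sample tests across subjects,
  # BH-corrected; false positives at most at the nominal rate on average
  set.seed(26)
  n_sub <- 8
  vals <- array(NA_real_, c(n_sub, 6, 3))
  for (s in seq_len(n_sub)) {
    ep <- tiny_epochs(n_per_cond = 6, n_channels = 6, n_samples = 3,
                      seed = 300 + s)
    m <- sensor_searchlight(ep, k = 2, bin_ms = 10, seed = s,
                            schemes = "within")
    vals[s, , ] <- m$maps$within
  }
  p <- apply(vals, c(2, 3), function(v) wilcoxon_signed_rank(v, mu = 50))
  rej <- fdr_bh(as.vector(p), q = 0.05)
  expect_lte(mean(rej), 0.05)
})
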