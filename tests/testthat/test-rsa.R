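test_that("RDMs are symmetric with an undefined diagonal", {
  vals <- seq_len(28)
  m <- rdm(vals)
  expect_identical(dim(unclass(m)), c(8L, 8L))
  expect_true(all(is.na(diag(m))))
  expect_equal(unclass(m)[upper.tri(m)], t(unclass(m))[upper.tri(m)])
  expect_identical(rdm_vec(m), as.numeric(vals))
  expect_error(rdm(1:10), "28 pair values")
  expect_error(rdm(matrix(1:64, 8, 8)), "symmetric")
})

test_that("accuracy RDMs place pairs correctly", {
  acc <- matrix(50, 2, 28)
  res <- braillemvpa:::new_decoding_result("within", acc)
  # constant accuracies: no representational structure, constant RDM
  m0 <- accuracies_to_rdm(res)
  expect_true(all(rdm_vec(m0) == 50))
  # single elevated pair (B, V) appears at (B,V) and (V,B) only
  pairs <- letter_pairs()
  bv <- which(pairs$a == "B" & pairs$b == "V")
  acc[, bv] <- 80
  m1 <- accuracies_to_rdm(braillemvpa:::new_decoding_result("within", acc))
  expect_equal(m1["B", "V"], 80)
  expect_equal(m1["V", "B"], 80)
  expect_true(all(rdm_vec(m1)[-bv] == 50))
  expect_identical(which.max(rdm_vec(m1)), as.integer(bv))
})

test_that("rating RDMs average participants", {
  r <- matrix(7L, 1, 28)
  class(r) <- c("similarity_ratings", "matrix")
  expect_true(all(rdm_vec(ratings_to_rdm(r)) == 7))
  r2 <- rbind(rep(3L, 28), rep(5L, 28))
  expect_true(all(rdm_vec(ratings_to_rdm(r2)) == 4))
  expect_error(ratings_to_rdm(matrix(9, 1, 28)), "1-7")
  expect_error(ratings_to_rdm(matrix(3, 1, 10)), "28 pair")
})

test_that("RDM Spearman correlation matches hand-worked rank arithmetic", {
  # distinct entries, no ties: R = 1 - 6 sum(d^2) / (n (n^2 - 1))
  set.seed(31)
  a <- sample(28)
  b <- sample(28)
  d <- rank(a) - rank(b)
  manual <- 1 - 6 * sum(d^2) / (28 * (28^2 - 1))
  expect_equal(rdm_correlation(rdm(a), rdm(b)), manual, tolerance = 1e-12)
  # identity and reversal
  expect_equal(rdm_correlation(rdm(a), rdm(a)), 1)
  expect_equal(rdm_correlation(rdm(a), rdm(29 - a)), -1)
})

test_that("Spearman R is invariant under strictly monotone transforms", {
  set.seed(32)
  a <- runif(28)
  b <- runif(28)
  r0 <- rdm_correlation(rdm(a), rdm(b))
  expect_equal(rdm_correlation(rdm(exp(3 * a)), rdm(b)), r0)
  expect_equal(rdm_correlation(rdm(a), rdm(b^3 + 10 * b)), r0)
  expect_equal(rdm_correlation(rdm(rank(a)), rdm(b)), r0)
})

test_that("zero-variance RDMs give an undefined correlation", {
  expect_warning(r <- rdm_correlation(rdm(rep(50, 28)), rdm(1:28)),
                 "zero variance")
  expect_true(is.na(r))
})

test_that("the group RSA pipeline has the prescribed shape", {
  # behavior RDM averaged over participants; neural RDMs subject-specific;
  # one R per subject and time point
  beh <- ratings_to_rdm(synthesize_similarity_ratings(n_participants = 4,
                                                      noise_sd = 0.5, seed = 1))
  n_sub <- 3; n_t <- 6
  set.seed(33)
  out <- matrix(NA_real_, n_sub, n_t)
  for (s in seq_len(n_sub)) {
    pa <- matrix(50 + rnorm(28 * n_t), 28, n_t)
    out[s, ] <- rsa_time_course(pa, beh)
  }
  expect_identical(dim(out), c(3L, 6L))
  expect_true(all(abs(out) <= 1))
})

test_that("planted geometry is recovered through the full neural RSA path", {
  # strong hand-independent code shaped by the pin geometry: the across-hand
  # accuracy RDM rank-correlates with the behavioral RDM
  spec <- effect_spec(sensory_snr = 1, perceptual_snr = 2.5, seed = 34)
  grp <- decode_group_time_courses(2, spec, seed = 35,
                                   trials_per_condition = 16,
                                   n_channels = 12,
                                   epoch_window_ms = c(-50, 340),
                                   n_iterations = 3, keep_pairs = TRUE)
  beh <- ratings_to_rdm(synthesize_similarity_ratings(noise_sd = 0,
                                                      n_participants = 2,
                                                      seed = 1))
  late <- grp$time_ms >= 200
  pa <- apply(grp$across_pairs[, , late, drop = FALSE], 2, mean)
  expect_gt(rdm_correlation(rdm(pa), beh), 0.6)
})

test_that("RDMs round-trip through labeled CSV", {
  m <- rdm(runif(28), source = "behavior")
  path <- tempfile(fileext = ".csv")
  write_rdm(m, path)
  m2 <- read_rdm(path)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(rownames(m2), braille_letters())
})
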