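test_that("the SVM solver reproduces a hand-worked max-margin solution", {
  # class +1 at (1,0), (1,1); class -1 at (-1,0), (-1,1): the separating
  # hyperplane is x = 0 with w = (1, 0), b = 0, margin planes x = +/-1
  Xtr <- rbind(c(1, 0), c(1, 1), c(-1, 0), c(-1, 1))
  ytr <- c(1, 1, -1, -1)
  Xte <- rbind(c(0.3, 5), c(-0.2, -7), c(2, 0))
  fit <- cpp_svm_linear(Xtr, ytr, Xte, C = 1)
  expect_equal(as.vector(fit$w), c(1, 0), tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(as.vector(fit$decision), Xte[, 1], tolerance = 1e-6)
})

test_that("the SVM solver agrees with libsvm on random tiny problems", {
  skip_if_not_installed("e1071")
  set.seed(42)
  agree <- 0
  n_prob <- 150
  for (i in seq_len(n_prob)) {
    f <- sample(2:10, 1)
    sep <- runif(1, 0, 1.5)
    Xtr <- matrix(rnorm(8 * f), 8, f) + rep(rep(c(1, -1), each = 4), f) * sep
    ytr <- rep(c(1, -1), each = 4)
    Xte <- matrix(rnorm(6 * f), 6, f)
    fit <- cpp_svm_linear(Xtr, ytr, Xte, C = 1)
    sv <- e1071::svm(Xtr, factor(ytr), kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(sv, Xte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")[, 1]
    if (colnames(attr(pred, "decision.values"))[1] == "-1/1") dv <- -dv
    agree <- agree + all(sign(fit$decision) == sign(dv))
  }
  expect_identical(agree, n_prob)
})

test_that("linearly separable clusters decode at 100%", {
  mu <- matrix(0, 16, 4)
  mu[, 1] <- rep(seq(0, 150, by = 10), length.out = 16)  # huge class separation
  pseudo <- tiny_pseudo(mu, noise_sd = 0.5, seed = 1)
  res <- within_hand_decode(pseudo)
  expect_true(all(res$acc == 100))
})

test_that("null data decodes at chance on average", {
  gm <- vapply(1:30, function(s) {
    grand_average(within_hand_decode(tiny_pseudo(matrix(0, 16, 6), seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(gm) - 50), 1)
})

test_that("a reduced letter set yields one pair per hand via pairwise_cv_decode", {
  set.seed(3)
  a <- matrix(rnorm(5 * 4), 5, 4) + 4
  b <- matrix(rnorm(5 * 4), 5, 4) - 4
  expect_equal(pairwise_cv_decode(a, b), 100)
  expect_error(pairwise_cv_decode(a, b[, 1:2]), "feature dimensionality")
  expect_error(pairwise_cv_decode(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "at least 2")
})

test_that("held-out folds are evaluated on the test-side data only", {
  set.seed(4)
  a <- matrix(rnorm(5 * 3), 5, 3) + 5
  b <- matrix(rnorm(5 * 3), 5, 3) - 5
  # swapping the test sides flips every prediction: accuracy 100 -> 0
  expect_equal(pairwise_cv_decode(a, b), 100)
  expect_equal(pairwise_cv_decode(a, b, test_a = b, test_b = a), 0)
})

test_that("within-hand results cover 28 pairs per hand", {
  pseudo <- tiny_pseudo(condition_means(5, sensory = 2, seed = 5), seed = 5)
  res <- within_hand_decode(pseudo)
  expect_identical(dim(res$acc), c(2L, 28L))
  expect_identical(dimnames(res$acc)$hand, c("left", "right"))
  expect_true(all(res$acc >= 0 & res$acc <= 100))
})

test_that("identical data in both hands makes across equal within exactly", {
  pseudo <- tiny_pseudo(condition_means(6, sensory = 1, seed = 6), seed = 6)
  pseudo[9:16, , ] <- pseudo[1:8, , ]
  w <- within_hand_decode(pseudo)
  x <- across_hand_decode(pseudo)
  expect_equal(unname(w$acc), unname(x$acc))
})

test_that("hand-swap symmetry holds for hand- and direction-averaged results", {
  pseudo <- tiny_pseudo(condition_means(6, sensory = 1.2, perceptual = 0.8,
                                        seed = 7), seed = 7)
  swapped <- pseudo[c(9:16, 1:8), , ]
  w1 <- hand_average(within_hand_decode(pseudo))
  w2 <- hand_average(within_hand_decode(swapped))
  x1 <- hand_average(across_hand_decode(pseudo))
  x2 <- hand_average(across_hand_decode(swapped))
  expect_equal(w1, w2)
  expect_equal(x1, x2)
})

test_that("hand-dependent vs hand-independent planted codes dissociate", {
  spec <- effect_spec(sensory_snr = 1.5, perceptual_snr = 1.5, seed = 11)
  ps <- synthesize_roi_patterns(n_runs = 10, spec = spec, n_features = 40,
                                mixes = c(tactile = 1, reading = 0))
  res <- roi_decode(ps, seed = 2, n_iterations = 10)
  # purely hand-dependent code: within above chance, across at chance
  expect_gt(grand_average(res$tactile$within), 65)
  expect_lt(abs(grand_average(res$tactile$across) - 50), 6)
  # purely hand-independent code: across informative, close to within
  expect_gt(grand_average(res$reading$across), 65)
  expect_lt(abs(grand_average(res$reading$within) -
                  grand_average(res$reading$across)), 6)
})

test_that("sensory score is the entrywise within-minus-across difference", {
  w <- braillemvpa:::new_decoding_result("within", matrix(75, 2, 28))
  x <- braillemvpa:::new_decoding_result("across", matrix(50, 2, 28))
  d <- sensory_score(w, x)
  expect_identical(d$scheme, "difference")
  expect_true(all(d$acc == 25))
  expect_true(all(sensory_score(w, w2 <- braillemvpa:::new_decoding_result(
    "across", matrix(75, 2, 28)))$acc == 0))
})

test_that("time-resolved decoding is deterministic under a fixed seed", {
  ep <- tiny_epochs(n_per_cond = 10, n_channels = 5, n_samples = 4, seed = 12)
  r1 <- time_resolved_decode(ep, n_iterations = 1, seed = 99)
  r2 <- time_resolved_decode(ep, n_iterations = 1, seed = 99)
  r3 <- time_resolved_decode(ep, n_iterations = 1, seed = 100)
  expect_identical(r1$within$acc, r2$within$acc)
  expect_false(identical(r1$within$acc, r3$within$acc))
  expect_error(time_resolved_decode(ep, n_iterations = 0), "at least 1")
})

test_that("planted onset timing is recovered by the decoding curve", {
  set.seed(13)
  pat <- matrix(rnorm(16 * 6), 16, 6) * 3
  ep <- tiny_epochs(n_per_cond = 10, n_channels = 6, n_samples = 8,
                    signal = function(cc) pat[cc, ], on_from = 5, seed = 13)
  dec <- time_resolved_decode(ep, n_iterations = 2, seed = 1,
                              schemes = "within")
  curve <- colMeans(hand_average(dec$within))
  expect_lt(max(curve[1:4]), 60)   # pre-onset: chance
  expect_gt(min(curve[5:8]), 90)   # post-onset: strong decoding
})

test_that("permuting letter labels within hand destroys decoding", {
  set.seed(14)
  pat <- matrix(rnorm(16 * 6), 16, 6) * 1.5
  gm <- vapply(1:20, function(s) {
    ep <- tiny_epochs(n_per_cond = 20, n_channels = 6, n_samples = 5,
                      signal = function(cc) pat[cc, ], on_from = 1, seed = s)
    # shuffle letters within each hand, independently per trial
    set.seed(1000 + s)
    for (h in c("left", "right")) {
      rows <- which(ep$labels$hand == h)
      ep$labels$letter[rows] <- sample(ep$labels$letter[rows])
    }
    dec <- time_resolved_decode(ep, n_iterations = 3, seed = s,
                                schemes = "within")
    mean(dec$within$acc)
  }, numeric(1))
  expect_lt(abs(mean(gm) - 50), 1)
})

test_that("within-hand accuracy does not decrease with sensory SNR", {
  snrs <- c(0, 0.6, 1.5)
  mean_acc <- vapply(snrs, function(snr) {
    mean(vapply(1:5, function(s) {
      pseudo <- tiny_pseudo(condition_means(6, sensory = snr, seed = s),
                            seed = 100 + s)
      grand_average(within_hand_decode(pseudo))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_acc) > -0.5))
  expect_gt(mean_acc[3], mean_acc[1] + 10)
})
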