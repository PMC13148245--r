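test_that("Shannon entropy matches direct histogram computation", {
  edges <- seq(0, 1, length.out = 11)
  expect_equal(shannon_entropy(rep(0.5, 100), edges), 0)
  uniform <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  expect_equal(shannon_entropy(uniform, edges), log(10))
  set.seed(31)
  w <- rnorm(1000)
  e2 <- global_bin_edges(w)
  expect_equal(shannon_entropy(w, e2), brute_shannon(w, e2), tolerance = 1e-12)
  expect_lte(shannon_entropy(w, e2), log(10))
  expect_gte(shannon_entropy(w, e2), 0)
})

test_that("Renyi entropy generalizes Shannon and is monotone in order", {
  edges <- seq(0, 2, length.out = 11)
  set.seed(32)
  w <- runif(500, 0, 2)
  expect_identical(renyi_entropy(w, edges, 1), shannon_entropy(w, edges))
  uniform <- rep(seq(0.1, 1.9, by = 0.2), each = 5)
  for (a in c(-5, -3, -1, 1, 3, 5)) {
    expect_equal(renyi_entropy(uniform, edges, a), log(10), tolerance = 1e-12)
  }
  # two-bin closed form, alpha = 3
  two <- c(rep(0.1, 9), 1.5)
  e2 <- c(0, 1, 2)
  expect_equal(renyi_entropy(two, e2, 3), log(0.9^3 + 0.1^3) / (1 - 3),
               tolerance = 1e-12)
  hs <- vapply(c(-5, -3, -1, 1, 3, 5), function(a) renyi_entropy(w, edges, a), 1.0)
  expect_true(all(diff(hs) <= 1e-9))
})

test_that("sample entropy equals the brute-force template count", {
  expect_true(is.na(sample_entropy(rep(0.7, 100))))
  alt <- rep(c(0, 1), 50)
  expect_equal(sample_entropy(alt), brute_sample_entropy(alt), tolerance = 1e-12)
  set.seed(33)
  w <- runif(200)
  expect_equal(sample_entropy(w), brute_sample_entropy(w), tolerance = 1e-12)
  expect_true(is.na(sample_entropy(c(1, 2))))
})

test_that("coarse graining is block averaging with the floor rule", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(coarse_grain(rep(2, 64), 8), rep(2, 8))
  expect_length(coarse_grain(seq_len(1001), 4), 250)
  expect_error(coarse_grain(1:3, 4), "shorter")
})

test_that("diffusion entropy recovers the ordinary and ballistic anchors", {
  ds <- vapply(1:5, function(s) { set.seed(s); dea(rnorm(2e4))$delta }, 1.0)
  expect_lt(abs(mean(ds) - 0.5), 0.05)

  expect_equal(dea(seq_len(5000))$delta, 1)           # deterministic ramp, capped
  set.seed(6)
  expect_equal(dea(cumsum(rnorm(2e4)))$delta, 1)      # persistent walk, capped
})

test_that("shuffling destroys correlations and restores ordinary diffusion", {
  set.seed(7)
  x <- cumsum(rnorm(2e4))
  ds <- vapply(1:5, function(s) { set.seed(s); dea(sample(x))$delta }, 1.0)
  expect_lt(abs(mean(ds) - 0.5), 0.05)
})

test_that("degenerate series yield flagged-missing DEA", {
  r <- dea(rep(1, 300))
  expect_true(is.na(r$delta))
  expect_true(is.na(r$mu_r))
  expect_error(dea(rnorm(100)), "256")
})

test_that("the delta/mu_r mapping and its inverse behave at the saturation cap", {
  expect_identical(mu_from_delta(1), 2)
  expect_identical(mu_from_delta(0.5), 3)
  expect_equal(mu_from_delta(0.656), 2.524, tolerance = 1e-3)
  expect_true(is.na(mu_from_delta(0)))
  expect_identical(delta_from_mu(2), 1)
  expect_identical(delta_from_mu(3), 0.5)
  expect_identical(delta_from_mu(1.5), 1)   # mu below 2 hits the cap
  expect_true(is.na(delta_from_mu(1)))
})

test_that("multiscale DEA returns one row per scale with length guards", {
  set.seed(8)
  x <- rnorm(3000)
  m <- msdea(x, scales = c(1, 4, 8, 16, 32, 128))
  expect_equal(m$scale, c(1, 4, 8, 16, 32, 128))
  expect_false(any(is.na(m$delta[1:2])))
  expect_true(all(is.na(m$delta[m$scale >= 16])))  # coarse series too short
})

test_that("sliding windows align to the right edge with the stated count", {
  sig <- sampled_signal(rep(1, 1100), 64)
  tr <- sliding_features(sig, win_len = 1000, step = 1, features = "shannon")
  expect_equal(nrow(tr), 101)
  expect_true(all(tr$value == 0))
  expect_equal(tr$time_s[1], 999 / 64)

  set.seed(9)
  stepsig <- sampled_signal(c(rnorm(600), rnorm(600, 10)), 64)
  tr2 <- sliding_features(stepsig, win_len = 200, step = 10, features = "shannon")
  pre <- tr2$value[tr2$time_s < 599 / 64]
  expect_lt(max(abs(diff(pre))), 0.3)  # stable away from the step

  expect_warning(empty <- sliding_features(sampled_signal(rnorm(10), 64),
                                           win_len = 1000),
                 "shorter")
  expect_equal(nrow(empty), 0)
})

test_that("entropies are invariant to affine rescaling with rescaled edges", {
  set.seed(10)
  w <- rnorm(500)
  edges <- global_bin_edges(w)
  w2 <- 3 * w + 7
  edges2 <- 3 * edges + 7
  expect_equal(shannon_entropy(w, edges), shannon_entropy(w2, edges2),
               tolerance = 1e-12)
  expect_equal(renyi_entropy(w, edges, 3), renyi_entropy(w2, edges2, 3),
               tolerance = 1e-12)
  expect_equal(sample_entropy(w), sample_entropy(w2), tolerance = 1e-12)
})
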