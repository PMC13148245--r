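test_that("the lag sign convention marks the leading signal", {
  x <- sin(2 * pi * (1:2000) / 160) + rnorm(2000, 0, 0.2)
  y <- c(rep(0, 10), x[1:1990])       # y echoes x 10 samples later
  pk <- peak_and_classify(xcorr_unbiased(x, y, 50))
  expect_equal(pk$lag_samples, 10L)
  expect_equal(pk$lag_class, "POS")
  expect_gt(pk$r_peak, 0.9)

  pk2 <- peak_and_classify(xcorr_unbiased(x, -x, 50))
  expect_equal(pk2$lag_samples, 0L)
  expect_equal(pk2$r_peak, -1)
  expect_equal(pk2$corr_class, "NEG")
  expect_equal(pk2$lag_class, "ZERO")
})

test_that("the normalization gives unit autocorrelation at zero lag", {
  set.seed(51)
  for (i in 1:5) {
    x <- rnorm(500) + seq(0, i, length.out = 500)
    xc <- xcorr_unbiased(x, x, 100)
    expect_equal(xc$curve$r[xc$curve$lag == 0], 1, tolerance = 1e-12)
    pk <- peak_and_classify(xc)
    expect_equal(pk$lag_samples, 0L)
  }
})

test_that("independent noise rarely exceeds the null correlation band", {
  set.seed(52)
  mx <- vapply(1:100, function(i) {
    max(abs(xcorr_unbiased(rnorm(2000), rnorm(2000), 320)$curve$r))
  }, 1.0)
  expect_gte(mean(mx < 0.15), 0.95)
})

test_that("the unbiased scaling keeps the null curve flat across lags", {
  set.seed(53)
  acc <- numeric(2 * 64 + 1)
  for (i in 1:40) {
    acc <- acc + abs(xcorr_unbiased(rnorm(1000), rnorm(1000), 64)$curve$r)
  }
  m <- acc / 40
  # mean |r(k)| should not trend with |k|
  expect_lt(abs(cor(m, abs(-64:64))), 0.35)
})

test_that("zero-variance input is flagged missing", {
  xc <- xcorr_unbiased(rep(1, 200), rnorm(200), 20)
  expect_true(xc$degenerate)
  pk <- peak_and_classify(xc)
  expect_true(is.na(pk$lag_s))
  expect_true(is.na(pk$lag_class))
})

test_that("exact |r| ties resolve to the smaller lag, then the negative one", {
  curve <- data.frame(lag = -10:10, r = 0)
  curve$r[curve$lag == 8] <- 0.5
  curve$r[curve$lag == -8] <- -0.5
  pk <- peak_and_classify(curve)
  expect_equal(pk$lag_samples, -8L)
  expect_equal(pk$corr_class, "NEG")

  curve$r[curve$lag == 3] <- 0.5
  expect_equal(peak_and_classify(curve)$lag_samples, 3L)
})

test_that("participant swap negates lags and preserves peak correlations", {
  sim <- quick_sim(seed = 54, duration = 300, regime_switching = FALSE)
  tracks <- lapply(sim$truth$beats, interpolate_rr, fs = 64, n = 300 * 64)
  seg <- segment_phases(sim$bundle$speak_mask$p1, sim$bundle$speak_mask$p2)
  fwd <- couple_session(tracks, seg)
  rev <- couple_session(rev(tracks), seg)
  expect_equal(fwd$lag_samples, -rev$lag_samples)
  expect_equal(fwd$r_peak, rev$r_peak, tolerance = 1e-12)
  expect_equal(fwd$lag_class, flip_lag_class(rev$lag_class))
})

test_that("session coupling recovers the injected lag and correlation signs", {
  lags <- c(); classes <- c()
  for (s in 1:5) {
    sim <- quick_sim(seed = s, duration = 300, couple_gain = 0.9,
                     regime_switching = FALSE)
    tracks <- lapply(sim$truth$beats, interpolate_rr, fs = 64, n = 300 * 64)
    seg <- segment_phases(sim$bundle$speak_mask$p1, sim$bundle$speak_mask$p2)
    cp <- couple_session(tracks, seg)
    cp <- cp[cp$phase == "simultaneous" & !is.na(cp$lag_s), ]
    lags <- c(lags, cp$lag_s)
    classes <- c(classes, cp$lag_class)
  }
  expect_gte(median(lags), 1)
  expect_lte(median(lags), 3)
  expect_gt(mean(classes == "POS"), 0.5)

  corr_cls <- c()
  for (s in 1:5) {
    sim <- quick_sim(seed = s, duration = 300, couple_gain = -0.8,
                     regime_switching = FALSE)
    tracks <- lapply(sim$truth$beats, interpolate_rr, fs = 64, n = 300 * 64)
    seg <- segment_phases(sim$bundle$speak_mask$p1, sim$bundle$speak_mask$p2)
    cp <- couple_session(tracks, seg)
    corr_cls <- c(corr_cls, cp$corr_class[!is.na(cp$corr_class)])
  }
  expect_gt(mean(corr_cls == "NEG"), 0.5)
})

test_that("short segments shrink the lag search and are flagged", {
  x <- sampled_signal(rnorm(64 * 8), 64)
  y <- sampled_signal(rnorm(64 * 8), 64)
  seg <- data.frame(segment_id = 1L, phase = "simultaneous", t_start = 0,
                    t_end = 8, speaker_id = "p1", listener_id = "p2",
                    purity = 1, kept = TRUE)
  cp <- couple_session(list(p1 = x, p2 = y), seg, max_lag = 5)
  expect_true(cp$shrunk)
  expect_equal(cp$max_lag_s, 2)
  expect_lte(abs(cp$lag_samples), 128)
})
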