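test_that("the PPG band-pass rejects drift, keeps the pulse band, kills DC", {
  fs <- 64
  t <- (0:(300 * fs - 1)) / fs
  drift <- sampled_signal(sin(2 * pi * 0.05 * t), fs)
  out <- bandpass_ppg(drift)
  expect_lt(sqrt(mean(out$values^2)) / sqrt(mean(drift$values^2)), 0.05)

  pulse <- sampled_signal(sin(2 * pi * 1.2 * t), fs)
  outp <- bandpass_ppg(pulse)
  mid <- (30 * fs):(270 * fs)
  expect_lt(abs(max(outp$values[mid]) - 1), 0.05)
  # zero phase: the filtered wave tracks the input sample for sample
  expect_lt(max(abs(outp$values[mid] - pulse$values[mid])), 0.06)

  dc <- sampled_signal(rep(3, 64 * 30), fs)
  expect_lt(max(abs(bandpass_ppg(dc)$values)), 1e-6)

  expect_error(bandpass_ppg(sampled_signal(rnorm(10), fs)), "short")
})

test_that("peak detection finds a 1 Hz train and keeps the taller of close peaks", {
  fs <- 64
  t <- (0:(60 * fs - 1)) / fs
  train <- sampled_signal(sin(2 * pi * t)^21, fs)  # sharp 1 Hz peaks
  b <- detect_peaks(train)
  expect_lt(abs(60 / mean(b$rr) - 60), 1)
  expect_true(all(abs(b$rr - 1) <= 1 / fs + 1e-9))

  # two candidates 0.3 s apart: only the taller survives
  v <- numeric(64 * 4)
  v[64] <- 1; v[64 + 19] <- 2; v[200] <- 1.5
  two <- detect_peaks(sampled_signal(v, fs))
  expect_true((64 + 19 - 1) %in% round(two$beat_times * fs))
  expect_false(63 %in% round(two$beat_times * fs))
})

test_that("no two retained peaks are closer than the minimum distance", {
  fs <- 64
  for (s in 1:5) {
    set.seed(s)
    sig <- sampled_signal(rnorm(fs * 30), fs)
    b <- detect_peaks(sig)
    if (length(b$rr)) expect_gte(min(b$rr), 0.4 - 1e-9)
  }
})

test_that("SDROM replaces outlying intervals by the local median and flags them", {
  b <- beat_series(cumsum(c(0.5, 0.8, 0.8, 1.6, 0.8, 0.8)))
  cb <- clean_rr_sdrom(b)
  expect_equal(cb$rr, rep(0.8, 5))
  expect_equal(sum(cb$flags == "corrected"), 1)

  const <- beat_series(cumsum(c(0.5, rep(0.8, 6))))
  expect_identical(clean_rr_sdrom(const)$rr, const$rr)
  expect_true(all(clean_rr_sdrom(const)$flags == "raw"))
})

test_that("SDROM cleaning is idempotent", {
  for (s in 1:5) {
    set.seed(s)
    rr <- abs(rnorm(80, 0.8, 0.05))
    rr[sample(80, 4)] <- rr[sample(80, 4)] * 2
    b <- beat_series(cumsum(c(0.2, rr)))
    once <- clean_rr_sdrom(b)
    twice <- clean_rr_sdrom(once)
    expect_equal(twice$rr, once$rr)
  }
})

test_that("SDROM flags injected ectopic-like spikes with few false alarms", {
  hits <- 0; n_spikes <- 0; false_flags <- 0; n_clean <- 0
  for (s in 1:10) {
    cfg <- dyad_config(duration = 300, seed = s)
    rr <- simulate_rr_pair(cfg)$beats$p1$rr
    m <- length(rr)
    idx <- sample(seq(3, m - 2), round(0.05 * m))
    rr_spiked <- rr
    rr_spiked[idx] <- rr_spiked[idx] * sample(c(0.55, 1.7), length(idx),
                                              replace = TRUE)
    b <- beat_series(cumsum(c(0.2, rr_spiked)))
    cb <- clean_rr_sdrom(b)
    flagged <- which(cb$flags[-1] == "corrected")
    hits <- hits + sum(idx %in% flagged)
    n_spikes <- n_spikes + length(idx)
    false_flags <- false_flags + sum(!(flagged %in% idx))
    n_clean <- n_clean + (m - length(idx))
  }
  expect_gte(hits / n_spikes, 0.9)
  expect_lte(false_flags / n_clean, 0.05)
})

test_that("RR interpolation is linear with held edges and fixed length", {
  b <- beat_series(c(0, 1, 2))
  tr <- interpolate_rr(b, 64, 64 * 3)
  expect_true(all(tr$values == 1))

  b2 <- beat_series(c(0, 0.8, 1.8))  # rr 0.8 then 1.0
  tr2 <- interpolate_rr(b2, 64, 64 * 2)
  midpoint <- (0.8 + 1.8) / 2
  expect_equal(tr2$values[round(midpoint * 64) + 1], 0.9, tolerance = 0.01)
  expect_length(tr2$values, 128)
  expect_error(interpolate_rr(beat_series(1), 64, 64), "2 beats")
})

test_that("respiration components are fused and the rate search stays in band", {
  cfg <- dyad_config(duration = 300, seed = 4, resp_rate = 0.3)
  sim <- simulate_dyad(cfg)
  cardio <- extract_cardio(sim$bundle)
  resp <- cardio$p1$respiration
  expect_s3_class(resp$composite, "sampled_signal")
  expect_named(resp$components, c("baseline", "amplitude", "frequency"))
  expect_lt(abs(resp$resp_rate - 0.3), 0.02)
  expect_gte(resp$resp_rate, 0.1)
  expect_lte(resp$resp_rate, 0.7)
})

test_that("amplitude modulation alone still reveals the respiration rate", {
  fs <- 64
  t <- (0:(240 * fs - 1)) / fs
  beats <- seq(0.2, 239, by = 0.8)
  v <- numeric(length(t))
  for (tb in beats) {
    idx <- which(abs(t - tb) < 0.2)
    v[idx] <- v[idx] + (1 + 0.2 * sin(2 * pi * 0.35 * tb)) *
      exp(-((t[idx] - tb)^2) / (2 * 0.06^2))
  }
  ppg <- sampled_signal(v, fs)
  rr_track <- sampled_signal(rep(0.8, length(t)), fs)  # flat: no RSA component
  resp <- derive_respiration(ppg, rr_track)
  expect_lt(abs(resp$resp_rate - 0.35), 0.03)
})

test_that("respiration output is invariant to the PPG amplitude scale", {
  cfg <- dyad_config(duration = 240, seed = 6)
  sim <- simulate_dyad(cfg)
  cardio <- extract_cardio(sim$bundle)
  ppg <- sim$bundle$ppg$p1
  scaled <- sampled_signal(ppg$values * 37, ppg$fs)
  r1 <- derive_respiration(ppg, cardio$p1$rr_track)
  r2 <- derive_respiration(scaled, cardio$p1$rr_track)
  expect_equal(r1$composite$values, r2$composite$values, tolerance = 1e-8)
})

test_that("covariate regression adjusts features and preserves scale", {
  set.seed(2)
  hr <- rnorm(30, 70, 5)
  f <- 2 * hr
  adj <- regress_out(f, data.frame(hr = hr))
  expect_equal(adj, rep(mean(f), 30))

  f2 <- rnorm(30)
  orth <- residuals(lm(rnorm(30) ~ f2))
  expect_equal(regress_out(f2, data.frame(c = orth)), f2, tolerance = 1e-10)

  # slope recovery within 2 SE
  x <- rnorm(100)
  y <- 1.5 * x + rnorm(100, 0, 0.3)
  fit <- lm(y ~ x)
  expect_lt(abs(coef(fit)[2] - 1.5), 2 * sqrt(diag(vcov(fit)))[2])

  # rank-deficient design drops the duplicated covariate
  expect_warning(out <- regress_out(f2, data.frame(a = x[1:30], b = x[1:30])),
                 "rank-deficient")
  expect_length(out, 30)
})
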