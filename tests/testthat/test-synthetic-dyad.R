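test_that("identical configurations reproduce sessions bit-identically", {
  a <- quick_sim(seed = 5, duration = 60)
  b <- quick_sim(seed = 5, duration = 60)
  expect_identical(a$bundle$ppg$p1$values, b$bundle$ppg$p1$values)
  expect_identical(a$bundle$speak_mask$p2$values, b$bundle$speak_mask$p2$values)
  expect_identical(a$bundle$emotion[[3]]$labels5s, b$bundle$emotion[[3]]$labels5s)
  c <- quick_sim(seed = 6, duration = 60)
  expect_false(identical(a$bundle$ppg$p1$values, c$bundle$ppg$p1$values))
})

test_that("pure-copy coupling limit shifts participant 1's RR process exactly", {
  cfg <- dyad_config(duration = 120, seed = 3, couple_gain = 1, couple_lag = 2,
                     hr_mean = c(75, 75), regime_switching = FALSE)
  rr <- simulate_rr_pair(cfg)
  idx <- (2 * 64 + 1):(120 * 64)
  expect_equal(rr$latent$p2$values[idx], rr$latent$p1$values[idx - 128])
})

test_that("uncoupled dyads show weak cross-correlation in expectation", {
  mx <- vapply(1:15, function(s) {
    cfg <- dyad_config(duration = 300, seed = s, couple_gain = 0,
                       regime_switching = FALSE)
    rr <- simulate_rr_pair(cfg)
    tr <- lapply(rr$beats, interpolate_rr, fs = 64, n = 300 * 64)
    max(abs(xcorr_unbiased(tr$p1$values, tr$p2$values, 320)$curve$r))
  }, 1.0)
  expect_lt(mean(mx), 0.2)
})

test_that("mean heart rate maps to mean RR within 1%", {
  cfg <- dyad_config(duration = 300, seed = 2, hr_mean = c(75, 60),
                     couple_gain = 0)  # uncoupled so both baselines are pure
  rr <- simulate_rr_pair(cfg)
  expect_lt(abs(mean(rr$beats$p1$rr) - 0.8) / 0.8, 0.01)
  expect_lt(abs(mean(rr$beats$p2$rr) - 1.0), 0.01)
})

test_that("noiseless PPG rendering lets peak detection recover every beat", {
  cfg <- dyad_config(duration = 120, seed = 7)
  rr <- simulate_rr_pair(cfg)
  ppg <- rr_to_ppg(rr$beats$p1, cfg, noise_sd = 0, drift_amp = 0)
  det <- detect_peaks(bandpass_ppg(ppg))
  truth <- rr$beats$p1$beat_times
  # match detected beats to true beats (ignore possible edge beats)
  interior <- truth[truth > 1 & truth < 119]
  err <- vapply(interior, function(tb) min(abs(det$beat_times - tb)), 1.0)
  expect_lte(max(err), 1 / 64 + 1e-9)
})

test_that("PPG amplitude modulation carries the respiration rate", {
  cfg <- dyad_config(duration = 300, seed = 8, resp_rate = 0.3)
  sim <- simulate_dyad(cfg)
  cardio <- extract_cardio(sim$bundle)
  expect_lt(abs(cardio$p1$respiration$resp_rate - 0.3), 0.02)
})

test_that("zero beats render as the deterministic baseline", {
  cfg <- dyad_config(duration = 10, seed = 1)
  ppg <- rr_to_ppg(beat_series(numeric()), cfg, noise_sd = 0)
  t <- (seq_len(640) - 1) / 64
  expect_equal(ppg$values, 0.3 * sin(2 * pi * 0.3 * t))
})

test_that("turn overlap probability controls simultaneous speech", {
  sp0 <- simulate_turns_and_speech(dyad_config(duration = 300, seed = 9,
                                               overlap_prob = 0))
  expect_equal(sum(sp0$speak_mask$p1$values * sp0$speak_mask$p2$values), 0)

  sp1 <- simulate_turns_and_speech(dyad_config(duration = 300, seed = 9,
                                               overlap_prob = 1))
  both <- sp1$speak_mask$p1$values * sp1$speak_mask$p2$values
  # every interior turn boundary gets at least one overlapping frame
  k <- nrow(sp1$turns)
  bounds <- sp1$turns$end_s[1:(k - 1)]
  bounds <- bounds[bounds < 299]
  hit <- vapply(bounds, function(b) {
    any(both[pmax(1, round(b * 64)):pmin(length(both), round(b * 64) + 32)] == 1)
  }, TRUE)
  expect_true(all(hit))
})

test_that("pitch tracks are clipped to the search range and gated by turns", {
  sp <- simulate_turns_and_speech(dyad_config(duration = 120, seed = 10))
  for (pid in c("p1", "p2")) {
    v <- sp$pitch[[pid]]$values
    expect_true(all(v == 0 | (v >= 50 & v <= 300)))
    expect_true(all(v[sp$speak_mask[[pid]]$values == 0] == 0))
  }
})

test_that("emotion generation honours degenerate bias and zero confusion", {
  cfg <- dyad_config(duration = 60, seed = 12, confusion = 0,
                     emotion_bias = list(POS = c(0, 0, 1, 0, 0),
                                         NEG = c(0, 0, 1, 0, 0)))
  reg <- sampled_signal(rep(1L, 60 * 64), 64)
  tracks <- simulate_emotions(cfg, reg)
  expect_true(all(unlist(lapply(tracks, `[[`, "labels5s")) == 3L))

  cfg2 <- dyad_config(duration = 60, seed = 13, confusion = 0)
  tracks2 <- simulate_emotions(cfg2, reg)
  self_a <- find_emotion_track(tracks2, "self", "arousal")
  partner_a <- find_emotion_track(tracks2, "partner", "arousal")
  expect_identical(self_a$labels5s, partner_a$labels5s)
})

test_that("simulated RR spectra show the HF peak at the respiration rate", {
  cfg <- dyad_config(duration = 300, seed = 14, resp_rate = 0.25)
  rr <- simulate_rr_pair(cfg)
  rrt <- interpolate_rr(rr$beats$p1, 4, 300 * 4)
  fd <- hrv_freq_domain(rrt)
  expect_lt(abs(fd$HF_peak - 0.25), 1 / 60 + 1e-9)
})

test_that("lag regimes are piecewise-constant over turns", {
  sp <- simulate_turns_and_speech(dyad_config(duration = 300, seed = 15))
  for (i in seq_len(nrow(sp$turns))) {
    lo <- floor(sp$turns$start_s[i] * 64) + 1
    hi <- min(length(sp$regime$values), floor(sp$turns$end_s[i] * 64))
    expect_true(all(sp$regime$values[lo:hi] == sp$turns$regime[i]))
  }
})
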