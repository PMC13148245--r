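#' Configuration of a synthetic dyadic session
#'
#' Defines the ground-truth generating process for a two-person debate-style
#' session: PPG-like pulse trains whose beat-interval (RR) series carry LF/HF
#' spectral structure and respiratory modulation, a tunable lead-lag coupling
#' between the participants' RR dynamics, alternating speaking turns with
#' optional overlap, speaker-gated pitch tracks, and 5-second emotion labels
#' whose distribution is conditioned on the momentary coupling regime.
#'
#' Defaults emulate a 10-minute seated, moderated debate between two adults:
#' heart rates near 72-75 bpm, respiration 0.3 Hz (18 breaths/min), LF
#' modulation near 0.1 Hz, a 2-second lead-lag with gain 0.7, and substantial
#' argument-length speaking turns (exponential, mean 25 s, floored at 18 s;
#' brief interjections appear as overlapping speech rather than as turns).
#' The turn-length floor is also an identifiability constraint: a +/- 2 s
#' lead-lag is only observable within exchanges several times that long.
#'
#' @param duration session length in seconds.
#' @param fs frame rate of the shared timeline (Hz).
#' @param hr_mean mean heart rate per participant (bpm), length 2.
#' @param lf_amp relative depth of the 0.1 Hz (LF, baroreflex-like) RR
#'   modulation.
#' @param hf_amp relative depth of the respiratory (HF) RR modulation.
#' @param resp_rate respiration rate in Hz, within `[0.1, 0.7]`.
#' @param couple_lag signed coupling lag in seconds; positive means
#'   participant 1 leads (participant 2 echoes later).
#' @param couple_gain coupling gain in `[-1, 1]`; negative values produce
#'   inverse (anti-phase) coupling.
#' @param rr_noise_sd SD of the white noise added to each latent RR track (s).
#' @param turn_len_mean mean speaking-turn length (s, exponential).
#' @param turn_len_min minimum speaking-turn length (s).
#' @param overlap_prob probability that a turn boundary carries overlapping
#'   speech.
#' @param regime_switching if `TRUE` (default) the lag sign flips randomly
#'   from speaking turn to speaking turn (piecewise-constant regime), so a
#'   session contains both leading and lagging episodes; if `FALSE` the sign
#'   of `couple_lag` holds throughout.
#' @param emotion_bias named list `POS`/`NEG`, each a probability vector over
#'   emotion states 1..5, giving the label distribution under each lag-sign
#'   regime. The default ties states 4-5 to the positive-lag regime and 1-2
#'   to the negative-lag regime; use [emotion_bias_null()] for no association.
#' @param confusion probability that a partner/external label deviates from
#'   the self label (by one step, clipped to 1..5).
#' @param pitch_median median pitch per participant (Hz), length 2.
#' @param seed integer seed; identical configurations reproduce sessions
#'   bit-identically.
#' @return an object of class `dyad_config`.
#' @export
dyad_config <- function(duration = 600, fs = 64,
                        hr_mean = c(75, 72),
                        lf_amp = 0.03, hf_amp = 0.025, resp_rate = 0.3,
                        couple_lag = 2, couple_gain = 0.7,
                        rr_noise_sd = 0.05,
                        turn_len_mean = 25, turn_len_min = 18,
                        overlap_prob = 0.2,
                        regime_switching = TRUE,
                        emotion_bias = emotion_bias_default(),
                        confusion = 0.2,
                        pitch_median = c(130, 180),
                        seed = 1L) {
  stopifnot(duration > 0, fs > 0, length(hr_mean) == 2L,
            abs(couple_gain) <= 1,
            resp_rate >= 0.1, resp_rate <= 0.7,
            overlap_prob >= 0, overlap_prob <= 1,
            confusion >= 0, confusion <= 1,
            all(c("POS", "NEG") %in% names(emotion_bias)))
  for (p in emotion_bias) {
    stopifnot(length(p) == 5L, all(p >= 0), sum(p) > 0)
  }
  structure(list(duration = duration, fs = fs, hr_mean = hr_mean,
                 lf_amp = lf_amp, hf_amp = hf_amp, resp_rate = resp_rate,
                 couple_lag = couple_lag, couple_gain = couple_gain,
                 rr_noise_sd = rr_noise_sd, turn_len_mean = turn_len_mean,
                 turn_len_min = turn_len_min, overlap_prob = overlap_prob,
                 regime_switching = regime_switching,
                 emotion_bias = lapply(emotion_bias, function(p) p / sum(p)),
                 confusion = confusion, pitch_median = pitch_median,
                 seed = as.integer(seed)),
            class = "dyad_config")
}

#' @rdname dyad_config
#' @export
emotion_bias_default <- function() {
  list(POS = c(0.05, 0.05, 0.10, 0.40, 0.40),
       NEG = c(0.40, 0.40, 0.10, 0.05, 0.05))
}

#' @rdname dyad_config
#' @export
emotion_bias_null <- function() {
  list(POS = rep(0.2, 5), NEG = rep(0.2, 5))
}

# deterministic per-component substream seeds (all well below 2^31)
substream_seed <- function(cfg, component) {
  offsets <- c(turns = 11L, rr = 23L, ppg = 37L, emotions = 53L)
  (cfg$seed %% 20000000L) * 100L + offsets[[component]]
}

#' Simulate alternating speaking turns, masks, intensity and pitch tracks
#'
#' Turn lengths are exponential with mean `turn_len_mean` (clamped to
#' `turn_len_min`-60 s); the speaker alternates. With probability `overlap_prob` a turn's
#' tail overlaps the start of the next turn by 0.2-1.5 s. A lag-sign regime
#' (+1/-1) is drawn per turn when `regime_switching` is on. Pitch during a
#' participant's own turns is lognormal around their median pitch, clipped to
#' 50-300 Hz, and 0 elsewhere; intensity is the speaking mask smoothed with a
#' 0.25-s moving average.
#'
#' @param cfg a [dyad_config()].
#' @return list with `turns` (data.frame `speaker, start_s, end_s, regime`),
#'   `speak_mask`, `intensity`, `pitch` (named lists of [sampled_signal()]s)
#'   and `regime` (frame-level +1/-1 [sampled_signal()]).
#' @export
simulate_turns_and_speech <- function(cfg) {
  stopifnot(inherits(cfg, "dyad_config"))
  set.seed(substream_seed(cfg, "turns"))
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  pids <- c("p1", "p2")

  starts <- c(); ends <- c(); speakers <- c()
  t <- 0; who <- 1L
  while (t < cfg$duration) {
    len <- min(60, max(cfg$turn_len_min, rexp(1, 1 / cfg$turn_len_mean)))
    starts <- c(starts, t); ends <- c(ends, min(cfg$duration, t + len))
    speakers <- c(speakers, pids[who])
    t <- t + len
    who <- 3L - who
  }
  k <- length(starts)
  regime_sign <- if (cfg$regime_switching) {
    ifelse(rbinom(k, 1, 0.5) == 1, 1L, -1L)
  } else rep(as.integer(sign(cfg$couple_lag)), k)
  if (all(regime_sign == 0L)) regime_sign[] <- 1L
  turns <- data.frame(speaker = speakers, start_s = starts, end_s = ends,
                      regime = regime_sign)

  # overlapping speech: extend a turn's speech into the next turn
  iv <- lapply(pids, function(p)
    turns[turns$speaker == p, c("start_s", "end_s"), drop = FALSE])
  names(iv) <- pids
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      if (runif(1) < cfg$overlap_prob) {
        ext <- runif(1, 0.2, 1.5)
        p <- turns$speaker[i]
        cap <- turns$end_s[i + 1L] - 0.1
        iv[[p]] <- rbind(iv[[p]],
                         data.frame(start_s = turns$end_s[i],
                                    end_s = min(cap, turns$end_s[i] + ext)))
      }
    }
  }
  speak_mask <- lapply(pids, function(p) {
    m <- merge_intervals(iv[[p]][iv[[p]]$end_s > iv[[p]]$start_s, , drop = FALSE])
    intervals_to_mask(m, fs, n)
  })
  names(speak_mask) <- pids

  win <- max(1L, round(0.25 * fs))
  intensity <- lapply(speak_mask, function(m) {
    cs <- cumsum(c(0, m$values))
    sm <- (cs[pmin(length(m$values), seq_along(m$values) + win %/% 2) + 1] -
             cs[pmax(0, seq_along(m$values) - 1 - win %/% 2) + 1]) /
      (pmin(length(m$values), seq_along(m$values) + win %/% 2) -
         pmax(0, seq_along(m$values) - 1 - win %/% 2))
    sampled_signal(sm, fs, 0, "intensity")
  })

  pitch <- lapply(seq_along(pids), function(i) {
    m <- speak_mask[[i]]$values
    v <- numeric(n)
    idx <- which(m == 1)
    if (length(idx) > 0L) {
      f0 <- rlnorm(length(idx), log(cfg$pitch_median[i]), 0.25)
      v[idx] <- pmin(300, pmax(50, f0))
    }
    sampled_signal(v, fs, 0, "pitch")
  })
  names(pitch) <- pids

  regime_frames <- integer(n)
  for (i in seq_len(k)) {
    lo <- time_to_frame(turns$start_s[i], fs)
    hi <- min(n, time_to_frame(turns$end_s[i], fs) - 1L)
    if (hi >= lo) regime_frames[lo:hi] <- turns$regime[i]
  }
  if (regime_frames[n] == 0L) regime_frames[n] <- turns$regime[k]
  list(turns = turns, speak_mask = speak_mask, intensity = intensity,
       pitch = pitch, regime = sampled_signal(regime_frames, fs, 0, "regime"))
}

#' Simulate a coupled pair of beat-interval series
#'
#' Participant 1's latent RR track is `60/hr_mean[1]` modulated by an LF
#' sinusoid near 0.1 Hz (participant-specific frequency in 0.08-0.12 Hz, so
#' uncoupled dyads decorrelate over a session), an HF sinusoid at the
#' respiration rate, and broadband noise smoothed over 0.5 s (band-limited,
#' so it survives beat-level sampling and carries the lag information).
#' Participant 2's track blends their own analogous process with
#' participant 1's track delayed by the (possibly regime-switching) coupling
#' lag: `rr2 = (1 - |g|) own + g rr1(t - lag)`, with the inverse-coupling
#' branch (`g < 0`) mirrored around participant 1's baseline so intervals
#' stay positive. Beat times are then obtained by integrating each latent
#' track (`t[k+1] = t[k] + rr(t[k])`).
#'
#' @param cfg a [dyad_config()].
#' @param regime optional frame-level +1/-1 [sampled_signal()] giving the lag
#'   sign over time (from [simulate_turns_and_speech()]); when `NULL` the
#'   sign of `couple_lag` is used throughout.
#' @return list with `beats` (named list of [beat_series()]), `latent` (named
#'   list of frame-level latent RR [sampled_signal()]s) and `regime`.
#' @export
simulate_rr_pair <- function(cfg, regime = NULL) {
  stopifnot(inherits(cfg, "dyad_config"))
  if (abs(cfg$couple_lag) > cfg$duration / 4) {
    stop("couple_lag exceeds duration/4; lag is not identifiable")
  }
  set.seed(substream_seed(cfg, "rr"))
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  t <- (seq_len(n) - 1) / fs
  base <- 60 / cfg$hr_mean
  phases <- runif(4, 0, 2 * pi)
  lf_freq <- runif(2, 0.08, 0.12)
  w <- max(1L, round(1.0 * fs))   # 1-s smoothing keeps the noise below the
                                  # beat-rate Nyquist so beat sampling carries it

  latent_own <- lapply(1:2, function(i) {
    noise <- as.numeric(stats::filter(rnorm(n), rep(1 / w, w), circular = TRUE))
    noise <- noise / sd(noise) * cfg$rr_noise_sd
    base[i] * (1 +
                 cfg$lf_amp * sin(2 * pi * lf_freq[i] * t + phases[2 * i - 1]) +
                 cfg$hf_amp * sin(2 * pi * cfg$resp_rate * t + phases[2 * i])) +
      noise
  })

  if (is.null(regime)) {
    sgn <- sign(cfg$couple_lag); if (sgn == 0) sgn <- 1
    regime_frames <- rep(as.integer(sgn), n)
  } else {
    regime_frames <- as.integer(regime$values)
    stopifnot(length(regime_frames) == n)
  }
  lag_frames <- regime_frames * round(abs(cfg$couple_lag) * fs)
  src <- pmin(n, pmax(1L, seq_len(n) - lag_frames))
  g <- cfg$couple_gain
  shifted1 <- latent_own[[1]][src]
  latent2 <- (1 - abs(g)) * latent_own[[2]] + g * shifted1 +
    (if (g < 0) 2 * abs(g) * base[1] else 0)

  latent <- list(p1 = sampled_signal(pmax(0.3, latent_own[[1]]), fs, 0, "latent_rr"),
                 p2 = sampled_signal(pmax(0.3, latent2), fs, 0, "latent_rr"))

  integrate_beats <- function(lat) {
    tb <- 0.2; times <- c()
    while (tb < cfg$duration) {
      times <- c(times, tb)
      tb <- tb + lat$values[min(n, time_to_frame(tb, fs))]
    }
    beat_series(times)
  }
  beats <- lapply(latent, integrate_beats)
  list(beats = beats, latent = latent,
       regime = sampled_signal(regime_frames, fs, 0, "regime"))
}

#' Render a beat series as a synthetic PPG waveform
#'
#' One Gaussian-shaped pulse (SD 60 ms) per beat on the 64 Hz timeline, with
#' pulse amplitude modulated at the respiration rate (depth 10%), a baseline
#' drift at the respiration rate (so baseline-wander respiration recovery is
#' testable) and additive white noise.
#'
#' @param beats a [beat_series()].
#' @param cfg a [dyad_config()].
#' @param noise_sd SD of the additive measurement noise.
#' @param am_depth amplitude-modulation depth at the respiration rate.
#' @param drift_amp amplitude of the respiratory baseline drift.
#' @return a PPG [sampled_signal()] of `duration * fs` frames.
#' @export
rr_to_ppg <- function(beats, cfg, noise_sd = 0.01, am_depth = 0.1,
                      drift_amp = 0.3) {
  stopifnot(inherits(cfg, "dyad_config"))
  set.seed(substream_seed(cfg, "ppg") + length(beats$beat_times))
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  t <- (seq_len(n) - 1) / fs
  v <- drift_amp * sin(2 * pi * cfg$resp_rate * t)
  pw <- 0.06                       # pulse SD in seconds
  half <- ceiling(3 * pw * fs)
  for (tb in beats$beat_times) {
    ctr <- (tb) * fs + 1
    lo <- max(1L, floor(ctr - half)); hi <- min(n, ceiling(ctr + half))
    if (hi < lo) next
    amp <- 1 + am_depth * sin(2 * pi * cfg$resp_rate * tb)
    idx <- lo:hi
    v[idx] <- v[idx] + amp * exp(-((t[idx] - tb)^2) / (2 * pw^2))
  }
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  sampled_signal(v, fs, 0, "ppg")
}

#' Simulate 5-second emotion annotations conditioned on the coupling regime
#'
#' For each 5-second window the lag-sign regime (majority over the window's
#' frames) selects the state distribution from `cfg$emotion_bias`; arousal
#' and valence are drawn independently from it for the self perspective.
#' Partner and external perspectives are noisy copies: with probability
#' `cfg$confusion` a label moves one step (clipped to 1..5).
#'
#' @param cfg a [dyad_config()].
#' @param regime frame-level +1/-1 [sampled_signal()].
#' @return list of six [emotion_track()]s (3 perspectives x 2 dimensions).
#' @export
simulate_emotions <- function(cfg, regime) {
  stopifnot(inherits(cfg, "dyad_config"))
  set.seed(substream_seed(cfg, "emotions"))
  fs <- cfg$fs
  n <- length(regime$values)
  per <- round(5 * fs)
  k <- ceiling(n / per)
  win_regime <- vapply(seq_len(k), function(i) {
    fr <- regime$values[(per * (i - 1) + 1):min(n, per * i)]
    if (sum(fr > 0) >= sum(fr < 0)) "POS" else "NEG"
  }, "")
  draw <- function() {
    vapply(win_regime, function(rg)
      sample(1:5, 1, prob = cfg$emotion_bias[[rg]]), 1L)
  }
  confuse <- function(x) {
    flip <- runif(length(x)) < cfg$confusion
    step <- ifelse(runif(length(x)) < 0.5, -1L, 1L)
    out <- ifelse(flip, pmin(5L, pmax(1L, x + step)), x)
    as.integer(out)
  }
  tracks <- list()
  for (dim in c("arousal", "valence")) {
    self <- draw()
    tracks[[length(tracks) + 1L]] <- emotion_track("self", dim, self, fs, n)
    tracks[[length(tracks) + 1L]] <- emotion_track("partner", dim, confuse(self), fs, n)
    tracks[[length(tracks) + 1L]] <- emotion_track("external", dim, confuse(self), fs, n)
  }
  tracks
}

#' Generate a complete synthetic dyadic session with ground truth
#'
#' Orchestrates [simulate_turns_and_speech()], [simulate_rr_pair()],
#' [rr_to_ppg()] and [simulate_emotions()] into a [session_bundle()] plus a
#' ground-truth record (turn table with per-turn lag regime, frame-level
#' regime, latent RR tracks, true beat series, coupling lag and gain).
#'
#' @param cfg a [dyad_config()].
#' @return list with elements `bundle` (a [session_bundle()]) and `truth`.
#' @export
simulate_dyad <- function(cfg) {
  stopifnot(inherits(cfg, "dyad_config"))
  sp <- simulate_turns_and_speech(cfg)
  rr <- simulate_rr_pair(cfg, regime = sp$regime)
  ppg <- lapply(rr$beats, rr_to_ppg, cfg = cfg)
  emotion <- simulate_emotions(cfg, sp$regime)
  bundle <- session_bundle(
    ppg = ppg, speak_mask = sp$speak_mask, intensity = sp$intensity,
    pitch = sp$pitch, emotion = emotion,
    meta = list(participants = c("p1", "p2"), fs = cfg$fs))
  truth <- list(turns = sp$turns, regime = sp$regime, latent = rr$latent,
                beats = rr$beats, couple_lag = cfg$couple_lag,
                couple_gain = cfg$couple_gain, resp_rate = cfg$resp_rate,
                cfg = cfg)
  list(bundle = bundle, truth = truth)
}

#' Write a simulated session and its ground truth to disk
#'
#' Writes the file layout [read_session()] consumes plus
#' `ground_truth.json` (turn table, coupling lag/gain, respiration rate,
#' seed).
#'
#' @param sim result of [simulate_dyad()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulated_session <- function(sim, dir) {
  write_session(sim$bundle, dir)
  gt <- list(turns = sim$truth$turns,
             couple_lag = sim$truth$couple_lag,
             couple_gain = sim$truth$couple_gain,
             resp_rate = sim$truth$resp_rate,
             seed = sim$truth$cfg$seed)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
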