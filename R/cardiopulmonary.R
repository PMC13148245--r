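#' Beat-time series with interbeat (RR) intervals
#'
#' Event-time representation of the pulse: beat times in seconds, successive
#' differences as RR intervals, and a per-beat quality flag (`"raw"`,
#' `"corrected"`).
#'
#' @param beat_times increasing numeric vector of beat times (s).
#' @param flags optional character flags, one per beat.
#' @return an object of class `beat_series` with fields `beat_times`, `rr`
#'   (length `length(beat_times) - 1`) and `flags`.
#' @export
beat_series <- function(beat_times, flags = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) >= 2L && any(diff(beat_times) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  if (is.null(flags)) flags <- rep("raw", length(beat_times))
  structure(list(beat_times = beat_times, rr = diff(beat_times), flags = flags),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series: %d beats, mean RR %.3f s, %d corrected>\n",
              length(x$beat_times),
              if (length(x$rr)) mean(x$rr) else NA_real_,
              sum(x$flags == "corrected")))
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$beat_times)

#' Band-pass filter a PPG signal (zero phase)
#'
#' A 4th-order Butterworth band-pass design applied forward-backward
#' (`signal::filtfilt`), i.e. zero phase with an effective 8th-order
#' magnitude response. Default band 0.5-5 Hz preserves the pulse rhythm
#' while attenuating motion artifacts and baseline drift.
#'
#' @param ppg a PPG [sampled_signal()].
#' @param low,high band edges in Hz.
#' @param order filter order of the underlying design.
#' @return filtered [sampled_signal()], same length as the input.
#' @export
bandpass_ppg <- function(ppg, low = 0.5, high = 5, order = 4) {
  stopifnot(inherits(ppg, "sampled_signal"))
  if (length(ppg$values) <= 3 * (2 * order + 1)) {
    stop("signal too short to band-pass filter")
  }
  if (ppg$fs <= 2 * high) stop("sampling rate must exceed twice the upper band edge")
  bf <- signal::butter(order, c(low, high) / (ppg$fs / 2), type = "pass")
  # the pass band excludes DC, so remove the mean up front (kills the
  # dominant step transient); odd-reflection padding suppresses the
  # remaining forward-backward edge transients
  v <- ppg$values - mean(ppg$values)
  n <- length(v)
  P <- min(n - 1L, round(3 * ppg$fs / low))
  padded <- c(2 * v[1] - rev(v[2:(P + 1L)]), v, 2 * v[n] - rev(v[(n - P):(n - 1L)]))
  out <- signal::filtfilt(bf, padded)[(P + 1L):(P + n)]
  signal_with(ppg, out, paste0(ppg$label, "_bp"))
}

#' Detect pulse peaks and derive RR intervals
#'
#' Local maxima subject to a minimum peak separation (default 0.4 s,
#' the spacing of a 150 bpm ceiling): when two candidate maxima fall within
#' the separation window the taller one wins.
#'
#' @param ppg filtered PPG [sampled_signal()].
#' @param min_dist minimum peak distance in seconds.
#' @param min_height minimum peak height; default 0 keeps all positive peaks
#'   of the band-passed (zero-mean) pulse wave.
#' @return a [beat_series()]; fewer than 2 peaks yields an empty RR vector
#'   with a warning.
#' @export
detect_peaks <- function(ppg, min_dist = 0.4, min_height = 0) {
  stopifnot(inherits(ppg, "sampled_signal"))
  v <- ppg$values
  n <- length(v)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] > min_height]
  gap <- max(1L, round(min_dist * ppg$fs))
  keep <- logical(n)
  for (i in cand[order(v[cand], decreasing = TRUE)]) {
    lo <- max(1L, i - gap + 1L); hi <- min(n, i + gap - 1L)
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  peaks <- which(keep)
  if (length(peaks) < 2L) {
    warning("detect_peaks: fewer than 2 peaks found; empty RR series")
    return(beat_series(ppg$t0 + (peaks - 1) / ppg$fs))
  }
  beat_series(ppg$t0 + (peaks - 1) / ppg$fs)
}

#' Clean RR intervals with a decision-based rank-order median (SDROM) filter
#'
#' Each RR interval is compared with the median of its surrounding window
#' (default 5 beats, centered, truncated at the edges); an interval deviating
#' from that median by more than `rel_thresh` times the median is replaced by
#' it and flagged `"corrected"`. The filter is idempotent. Beat times are
#' rebuilt from the cleaned intervals (first beat anchored).
#'
#' @param beats a [beat_series()].
#' @param window window length in beats (odd; default 5).
#' @param rel_thresh relative deviation threshold (default 0.2).
#' @return cleaned [beat_series()] with updated flags.
#' @export
clean_rr_sdrom <- function(beats, window = 5, rel_thresh = 0.2) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$rr
  m <- length(rr)
  if (m < window) {
    warning("clean_rr_sdrom: series shorter than window; passed through")
    return(beats)
  }
  half <- window %/% 2
  med <- vapply(seq_len(m), function(i) {
    lo <- max(1L, i - half); hi <- min(m, i + half)
    median(rr[lo:hi])
  }, 1.0)
  bad <- abs(rr - med) > rel_thresh * med
  rr[bad] <- med[bad]
  times <- beats$beat_times[1] + c(0, cumsum(rr))
  flags <- c("raw", ifelse(bad, "corrected", "raw"))
  beat_series(times, flags)
}

#' Interpolate RR intervals to a frame-level track
#'
#' Each interval's value is anchored at the beat that closes it and linearly
#' interpolated to every frame of the target timeline; frames before the
#' first and after the last anchored beat hold the edge values.
#'
#' @param beats a [beat_series()] with at least 2 beats.
#' @param fs frame rate (Hz, default 64).
#' @param n number of output frames.
#' @param t0 time of the first frame (s).
#' @return RR [sampled_signal()] of length `n` (seconds).
#' @export
interpolate_rr <- function(beats, fs = 64, n, t0 = 0) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$beat_times) < 2L) stop("need at least 2 beats to interpolate RR")
  tt <- t0 + (seq_len(n) - 1) / fs
  anchors <- beats$beat_times[-1]
  v <- approx(anchors, beats$rr, xout = tt, rule = 2)$y
  sampled_signal(v, fs, t0, "rr")
}

# analytic-signal magnitude via FFT (the discrete Hilbert envelope)
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# band-pass on a decimated 4 Hz timeline; the 0.1-0.7 Hz band is numerically
# unstable for filtfilt at fs = 64 (normalized edge 0.003), so decimate first
resp_band_filter <- function(sig, low = 0.1, high = 0.7, fs_work = 4) {
  s4 <- resample_signal(sig, fs_work)
  bf <- signal::butter(4, c(low, high) / (fs_work / 2), type = "pass")
  signal_with(s4, signal::filtfilt(bf, s4$values), paste0(sig$label, "_resp"))
}

#' Derive a composite respiration signal from PPG
#'
#' Three respiratory mechanisms are extracted and band-limited to
#' 0.1-0.7 Hz: (1) baseline wander of the raw PPG, (2) amplitude modulation
#' of the pulse wave, measured as the analytic-signal (Hilbert) envelope of
#' the band-passed PPG, and (3) frequency modulation (respiratory sinus
#' arrhythmia), i.e. the frame-level RR track. Each component is z-normalized
#' and the composite is their arithmetic mean; the respiration rate is the
#' dominant Welch spectral peak of the composite within 0.1-0.7 Hz.
#'
#' @param ppg raw PPG [sampled_signal()].
#' @param rr_track frame-level RR [sampled_signal()] on the same timeline.
#' @return list of class `respiration_signal`: `composite` (4 Hz
#'   [sampled_signal()]), `components` (named list), `resp_rate` (Hz, `NA`
#'   if all components are flat).
#' @export
derive_respiration <- function(ppg, rr_track) {
  stopifnot(inherits(ppg, "sampled_signal"), inherits(rr_track, "sampled_signal"))
  ppg_bp <- bandpass_ppg(ppg)
  comp <- list(
    baseline = resp_band_filter(ppg),
    amplitude = resp_band_filter(signal_with(ppg_bp, hilbert_envelope(ppg_bp$values))),
    frequency = resp_band_filter(rr_track)
  )
  zs <- lapply(comp, function(s) {
    z <- znorm_pop(s$values)
    if (anyNA(z)) z <- rep(0, length(s$values))  # flat component
    z
  })
  len <- min(vapply(zs, length, 1L))
  composite <- sampled_signal(rowMeans(vapply(zs, function(z) z[seq_len(len)],
                                              numeric(len))),
                              comp[[1]]$fs, ppg$t0, "respiration")
  rate <- NA_real_
  if (sd_pop(composite$values) > 0) {
    ps <- welch_psd(composite$values, composite$fs, seg_len_s = 60)
    band <- ps$freq >= 0.1 & ps$freq <= 0.7
    if (any(band)) rate <- ps$freq[band][which.max(ps$psd[band])]
  }
  structure(list(composite = composite, components = comp, resp_rate = rate),
            class = "respiration_signal")
}

#' Remove covariate-driven variance from per-segment feature values
#'
#' Ordinary least-squares of a feature on covariates (typically segment mean
#' heart rate and/or respiration rate), fitted per participant; returns the
#' residual plus the participant mean so the feature keeps its scale.
#' Covariates that make the design rank deficient are dropped with a warning.
#'
#' @param feature numeric vector of per-segment feature values.
#' @param covariates data.frame (or vector) of covariates, same length.
#' @param participant factor/character of participant ids, same length;
#'   default treats all values as one participant.
#' @return numeric vector of adjusted values.
#' @export
regress_out <- function(feature, covariates, participant = NULL) {
  covariates <- as.data.frame(covariates)
  if (is.null(participant)) participant <- rep("all", length(feature))
  out <- rep(NA_real_, length(feature))
  for (pid in unique(participant)) {
    idx <- which(participant == pid & !is.na(feature))
    if (length(idx) < 3L) {
      warning("regress_out: fewer than 3 segments for participant ", pid,
              "; values passed through")
      out[participant == pid] <- feature[participant == pid]
      next
    }
    d <- cbind(.y = feature[idx], covariates[idx, , drop = FALSE])
    fit <- lm(.y ~ ., data = d)
    if (anyNA(coef(fit))) {
      keep <- names(coef(fit))[!is.na(coef(fit))]
      keep <- setdiff(keep, "(Intercept)")
      warning("regress_out: dropped rank-deficient covariate(s) for ", pid)
      d2 <- d[, c(".y", intersect(names(d), keep)), drop = FALSE]
      fit <- lm(.y ~ ., data = d2)
    }
    out[idx] <- residuals(fit) + mean(feature[idx])
  }
  out
}
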