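#' Pitch extraction by normalized cross-correlation
#'
#' Classic NCF pitch tracking: for each 40-ms analysis frame the normalized
#' cross-correlation of the frame with itself is evaluated over candidate
#' lags spanning the 50-300 Hz search range; the lag of the NCF maximum gives
#' `f0 = fs / lag`. Frames whose NCF peak falls below the voicing threshold
#' are marked unvoiced (pitch 0). The frame-rate track is then resampled to
#' the shared 64 Hz timeline by nearest neighbour.
#'
#' @param audio mono audio [sampled_signal()]; the sampling rate must be at
#'   least 8 kHz so the shortest candidate lag is resolvable.
#' @param frame analysis window length in seconds (default 0.040).
#' @param hop frame hop in seconds (default 0.010).
#' @param fmin,fmax pitch search range in Hz (default 50-300).
#' @param voicing_threshold minimum NCF peak for a voiced frame (default 0.3).
#' @param fs_out output frame rate (default 64 Hz).
#' @return a pitch [sampled_signal()] at `fs_out`; 0 marks unvoiced frames,
#'   nonzero values lie in `[fmin, fmax]`.
#' @export
pitch_ncf <- function(audio, frame = 0.040, hop = 0.010, fmin = 50, fmax = 300,
                      voicing_threshold = 0.3, fs_out = 64) {
  stopifnot(inherits(audio, "sampled_signal"))
  fs <- audio$fs
  if (fs < 8000) stop("audio sampling rate too low for NCF pitch (need >= 8 kHz)")
  v <- audio$values
  W <- round(frame * fs)
  H <- max(1L, round(hop * fs))
  lag_min <- max(2L, floor(fs / fmax))
  lag_max <- ceiling(fs / fmin)
  if (W <= lag_max) stop("analysis window shorter than the longest pitch lag")
  starts <- seq(1L, length(v) - W + 1L, by = H)
  lags <- lag_min:lag_max
  f0 <- vapply(starts, function(s) {
    x <- v[s:(s + W - 1L)]
    if (sd_pop(x) == 0) return(0)
    x <- x - mean(x)
    ncf <- vapply(lags, function(k) {
      a <- x[1:(W - k)]; b <- x[(k + 1):W]
      den <- sqrt(sum(a^2) * sum(b^2))
      if (den == 0) -Inf else sum(a * b) / den
    }, 1.0)
    best <- max(ncf)
    if (!is.finite(best) || best < voicing_threshold) return(0)
    # octave-error guard: among local NCF maxima within 0.02 of the global
    # maximum, take the shortest lag (the true period, not a multiple)
    m <- length(ncf)
    is_max <- c(ncf[1] >= ncf[2],
                ncf[2:(m - 1)] > ncf[1:(m - 2)] & ncf[2:(m - 1)] >= ncf[3:m],
                ncf[m] > ncf[m - 1])
    cand <- which(is_max & ncf >= best - 0.02)
    i <- cand[1]
    k <- lags[i]
    if (i > 1L && i < m) {   # parabolic sub-sample refinement
      denom <- ncf[i - 1] - 2 * ncf[i] + ncf[i + 1]
      if (is.finite(denom) && denom < 0) {
        k <- k + 0.5 * (ncf[i - 1] - ncf[i + 1]) / denom
      }
    }
    fs / k
  }, 1.0)
  t_frame <- audio$t0 + (starts - 1L + W / 2) / fs
  n_out <- max(1L, round((length(v) / fs) * fs_out))
  t_out <- audio$t0 + (seq_len(n_out) - 1) / fs_out
  idx <- vapply(t_out, function(t) which.min(abs(t_frame - t)), 1L)
  sampled_signal(f0[idx], fs_out, audio$t0, "pitch")
}

#' Align a pitch track to an intensity trace
#'
#' Window-based pitch detection can offset the pitch track against the
#' physiological timeline; the shift (within +/- `max_shift`) that maximizes
#' the correlation between the voicing indicator and the intensity trace is
#' found and applied. A flat intensity trace yields zero shift with a
#' warning.
#'
#' @param pitch pitch [sampled_signal()] (0 = unvoiced).
#' @param intensity intensity [sampled_signal()] on the same timeline.
#' @param max_shift maximum shift magnitude in seconds (default 1).
#' @return shifted pitch [sampled_signal()]; the applied shift in frames is
#'   stored in attribute `shift_frames` (positive = track moved later).
#' @export
align_pitch <- function(pitch, intensity, max_shift = 1) {
  stopifnot(inherits(pitch, "sampled_signal"), inherits(intensity, "sampled_signal"))
  fs <- pitch$fs
  K <- round(max_shift * fs)
  n <- min(length(pitch$values), length(intensity$values))
  voic <- as.numeric(pitch$values[seq_len(n)] > 0)
  inten <- intensity$values[seq_len(n)]
  if (sd_pop(inten) == 0 || sd_pop(voic) == 0) {
    if (sd_pop(inten) == 0) warning("align_pitch: flat intensity; zero shift")
    out <- pitch
    attr(out, "shift_frames") <- 0L
    return(out)
  }
  score <- vapply(-K:K, function(k) {
    if (k >= 0) {
      a <- voic[1:(n - k)]; b <- inten[(1 + k):n]
    } else {
      a <- voic[(1 - k):n]; b <- inten[1:(n + k)]
    }
    if (sd_pop(a) == 0 || sd_pop(b) == 0) return(-Inf)
    sum(znorm_pop(a) * znorm_pop(b)) / length(a)
  }, 1.0)
  # score(k) compares voicing at t with intensity at t+k; the maximizing k is
  # the shift that, applied to the pitch track, aligns it with the intensity
  # (negative = the track was delayed and is moved earlier)
  shift <- (-K:K)[order(-score, abs(-K:K))][1]
  v <- pitch$values
  out_v <- numeric(length(v))
  if (shift >= 0) {
    out_v[(1 + shift):length(v)] <- v[1:(length(v) - shift)]
  } else {
    out_v[1:(length(v) + shift)] <- v[(1 - shift):length(v)]
  }
  out <- signal_with(pitch, out_v)
  attr(out, "shift_frames") <- as.integer(shift)
  out
}

#' Gate a pitch track by a speaking mask
#'
#' Zeroes pitch values wherever the participant's speaking mask is 0, giving
#' a speaker-attributed pitch signal. Idempotent.
#'
#' @param pitch pitch [sampled_signal()].
#' @param mask binary speaking-mask [sampled_signal()] on the same timeline.
#' @return gated pitch [sampled_signal()].
#' @export
gate_by_speaker <- function(pitch, mask) {
  stopifnot(inherits(pitch, "sampled_signal"), inherits(mask, "sampled_signal"))
  n <- min(length(pitch$values), length(mask$values))
  v <- numeric(length(pitch$values))
  v[seq_len(n)] <- pitch$values[seq_len(n)] * (mask$values[seq_len(n)] != 0)
  signal_with(pitch, v)
}

#' Distribution statistics of a gated pitch window
#'
#' Statistics are computed over voiced (nonzero) samples only: mean and
#' sample SD, adjusted Fisher-Pearson skewness, non-excess kurtosis (normal
#' = 3), and Shannon entropy over 10 equal-width bins spanning the 50-300 Hz
#' search range (fixed edges, so pitch entropy is comparable across
#' speakers). Windows with fewer than `min_voiced` voiced samples are
#' flagged missing.
#'
#' @param window numeric vector of gated pitch values (0 = unvoiced).
#' @param min_voiced minimum voiced sample count (default 50).
#' @param range pitch range for the entropy bins (default `c(50, 300)`).
#' @return named list `mean`, `sd`, `skewness`, `kurtosis`, `entropy`
#'   (all `NA` when under-voiced; skewness/kurtosis `NA` for zero-variance
#'   windows).
#' @export
pitch_window_stats <- function(window, min_voiced = 50, range = c(50, 300)) {
  voiced <- window[window > 0 & is.finite(window)]
  out <- list(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
              kurtosis = NA_real_, entropy = NA_real_)
  if (length(voiced) < min_voiced) return(out)
  out$mean <- mean(voiced)
  out$sd <- sd(voiced)
  if (out$sd > 0) {
    out$skewness <- e1071::skewness(voiced, type = 2)
    out$kurtosis <- e1071::kurtosis(voiced, type = 1) + 3
  }
  edges <- seq(range[1], range[2], length.out = 11L)
  out$entropy <- shannon_entropy(voiced, edges)
  out
}
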