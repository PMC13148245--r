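#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed segments (default 60 s) with
#' 50% overlap, one-sided density scaling so that the integral of the PSD
#' over frequency equals the signal variance. Inputs shorter than one segment
#' fall back to a single full-length periodogram with a flag.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param seg_len_s segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz), `psd` (power density), `n_segments`,
#'   `short_flag`.
#' @export
welch_psd <- function(x, fs, seg_len_s = 60, overlap = 0.5) {
  n <- length(x)
  seg <- round(seg_len_s * fs)
  short_flag <- FALSE
  if (n < seg) {
    seg <- n
    short_flag <- TRUE
  }
  hop <- max(1L, round(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))   # Hann
  U <- sum(w^2)
  nf <- seg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)] * w
    P <- Mod(fft(xs))^2 / (fs * U)
    half <- P[seq_len(nf)]
    half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    if (seg %% 2 == 1L) half[nf] <- 2 * half[nf]
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg, psd = acc / length(starts),
       n_segments = length(starts), short_flag = short_flag)
}

#' Time-domain HRV panel
#'
#' @param rr numeric RR intervals in seconds.
#' @return named list: `AVNN` (s), `SDNN` (sample SD, s), `RMSSD` (s),
#'   `pNN50` (%), `SEM` (s). Members undefined for the given length are `NA`.
#' @export
hrv_time_domain <- function(rr) {
  rr <- rr[!is.na(rr)]
  n <- length(rr)
  out <- list(AVNN = NA_real_, SDNN = NA_real_, RMSSD = NA_real_,
              pNN50 = NA_real_, SEM = NA_real_)
  if (n >= 2L) {
    out$AVNN <- mean(rr)
    out$SDNN <- sd(rr)
    out$SEM <- out$SDNN / sqrt(n)
  }
  if (n >= 3L) {
    d <- diff(rr)
    out$RMSSD <- sqrt(mean(d^2))
    out$pNN50 <- 100 * sum(abs(d) > 0.05) / length(d)
  }
  out
}

hrv_bands <- function() {
  list(VLF = c(0.0033, 0.04), LF = c(0.04, 0.15), HF = c(0.15, 0.4))
}

band_power <- function(freq, psd, lo, hi) {
  lo <- max(lo, min(freq)); hi <- min(hi, max(freq))
  if (hi <= lo) return(list(power = 0, peak = NA_real_))
  inner <- freq[freq > lo & freq < hi]
  xs <- c(lo, inner, hi)               # interpolate the PSD at the band edges
  ys <- approx(freq, psd, xout = xs)$y # so narrow bands are not truncated
  idx <- which(freq >= lo & freq <= hi)
  peak <- if (length(idx)) freq[idx][which.max(psd[idx])] else NA_real_
  list(power = pracma::trapz(xs, ys), peak = peak)
}

#' Frequency-domain HRV panel
#'
#' The RR track is linearly detrended, resampled to 4 Hz and analysed with
#' [welch_psd()] (60-s Hann segments, 50% overlap). Band powers are
#' trapezoidal integrals over VLF 0.0033-0.04, LF 0.04-0.15 and HF
#' 0.15-0.4 Hz; normalized LF/HF powers are percentages of LF+HF.
#'
#' @param rr_track frame-level RR [sampled_signal()] (any rate; resampled
#'   internally).
#' @param seg_len_s Welch segment length (s).
#' @return named list: absolute powers `VLF`, `LF`, `HF` (s^2), peak
#'   frequencies `VLF_peak`, `LF_peak`, `HF_peak` (Hz), `LF_norm`, `HF_norm`
#'   (%), `LF_HF` ratio, `total_power` (s^2), `short_flag`.
#' @export
hrv_freq_domain <- function(rr_track, seg_len_s = 60) {
  stopifnot(inherits(rr_track, "sampled_signal"))
  s4 <- resample_signal(rr_track, 4)
  v <- detrend_linear(s4$values)
  if (sd_pop(v) == 0) {
    return(list(VLF = 0, LF = 0, HF = 0,
                VLF_peak = NA_real_, LF_peak = NA_real_, HF_peak = NA_real_,
                LF_norm = NA_real_, HF_norm = NA_real_, LF_HF = NA_real_,
                total_power = 0, short_flag = length(v) < round(seg_len_s * 4)))
  }
  ps <- welch_psd(v, 4, seg_len_s = seg_len_s)
  bands <- hrv_bands()
  bp <- lapply(bands, function(b) band_power(ps$freq, ps$psd, b[1], b[2]))
  tot <- band_power(ps$freq, ps$psd, 0.0033, 0.4)$power
  lf <- bp$LF$power; hf <- bp$HF$power
  list(VLF = bp$VLF$power, LF = lf, HF = hf,
       VLF_peak = bp$VLF$peak, LF_peak = bp$LF$peak, HF_peak = bp$HF$peak,
       LF_norm = if (lf + hf > 0) 100 * lf / (lf + hf) else NA_real_,
       HF_norm = if (lf + hf > 0) 100 * hf / (lf + hf) else NA_real_,
       LF_HF = if (hf > 0) lf / hf else NA_real_,
       total_power = tot, short_flag = ps$short_flag)
}

#' Poincare plot dispersions SD1 and SD2
#'
#' SD1 is the dispersion of successive differences around zero divided by
#' sqrt(2) — the uncentered (second-moment) convention, which makes
#' `SD1 = RMSSD / sqrt(2)` an exact algebraic identity. SD2 is derived from
#' the population SDNN via `SD2^2 = 2 SDNN_pop^2 - SD1_c^2` with the centred
#' short-axis term, floored at zero.
#'
#' @param rr numeric RR intervals (s), at least 3.
#' @return list `SD1`, `SD2` (s); `NA` if too few intervals.
#' @export
poincare <- function(rr) {
  rr <- rr[!is.na(rr)]
  if (length(rr) < 3L) return(list(SD1 = NA_real_, SD2 = NA_real_))
  d <- diff(rr)
  sd1 <- sqrt(mean(d^2) / 2)
  sd1c2 <- mean((d - mean(d))^2) / 2
  sd2 <- sqrt(max(0, 2 * mean((rr - mean(rr))^2) - sd1c2))
  list(SD1 = sd1, SD2 = sd2)
}

#' Detrended fluctuation analysis of RR intervals
#'
#' The mean-centered series is integrated; for each box size the profile is
#' split into non-overlapping boxes, each box is linearly detrended, and
#' F(n) is the RMS residual. `alpha1` is the log-log slope over boxes of
#' 4-11 beats, `alpha2` over 12-64 beats.
#'
#' @param rr numeric RR intervals.
#' @param short_range integer box sizes for alpha1.
#' @param long_range integer box sizes for alpha2.
#' @return list `alpha1`, `alpha2` (each `NA` when the series is too short:
#'   alpha1 needs >= 32 intervals, alpha2 >= 128).
#' @export
dfa <- function(rr, short_range = 4:11,
                long_range = unique(round(exp(seq(log(12), log(64), length.out = 10))))) {
  rr <- rr[!is.na(rr)]
  N <- length(rr)
  fluct <- function(box_sizes) {
    y <- cumsum(rr - mean(rr))
    Fn <- vapply(box_sizes, function(bs) {
      nb <- N %/% bs
      if (nb < 2L) return(NA_real_)
      m <- matrix(y[seq_len(nb * bs)], nrow = bs)
      tt <- seq_len(bs)
      X <- cbind(1, tt)
      H <- X %*% solve(crossprod(X), t(X))
      resid <- m - H %*% m
      sqrt(mean(resid^2))
    }, 1.0)
    ok <- !is.na(Fn) & Fn > 0
    if (sum(ok) < 3L) return(NA_real_)
    unname(coef(lm(log(Fn[ok]) ~ log(box_sizes[ok])))[2])
  }
  list(alpha1 = if (N >= 32L) fluct(short_range) else NA_real_,
       alpha2 = if (N >= 128L) fluct(long_range) else NA_real_)
}

#' Full HRV panel for one RR segment
#'
#' Combines [hrv_time_domain()], [poincare()], [dfa()] and — when a
#' frame-level RR track is supplied and long enough — [hrv_freq_domain()].
#'
#' @param rr numeric RR intervals (s).
#' @param rr_track optional frame-level RR [sampled_signal()] for the same
#'   span (needed for the frequency-domain members).
#' @return named list of panel members (`NA` where undefined).
#' @export
hrv_panel <- function(rr, rr_track = NULL) {
  out <- hrv_time_domain(rr)
  out <- c(out, poincare(rr))
  out <- c(out, dfa(rr))
  if (!is.null(rr_track)) {
    out <- c(out, hrv_freq_domain(rr_track))
  }
  out
}
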