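#' Uniformly sampled time series
#'
#' The basic carrier for every stream in the package: raw PPG, interpolated RR,
#' respiration components, speaking masks, intensity traces, pitch tracks and
#' windowed feature tracks. Sample `i` (0-based) sits at time `t0 + i/fs`.
#'
#' @param values numeric vector of samples; `NA` marks flagged-missing samples.
#' @param fs sampling rate in Hz, must be positive.
#' @param t0 time of the first sample in seconds.
#' @param label free-text description of the stream.
#' @return An object of class `sampled_signal` with fields `values`, `fs`,
#'   `t0`, `label`.
#' @export
sampled_signal <- function(values, fs, t0 = 0, label = "") {
  stopifnot(is.numeric(values), length(fs) == 1L, fs > 0)
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         t0 = as.numeric(t0), label = as.character(label)),
    class = "sampled_signal"
  )
}

#' Sample times of a sampled signal
#'
#' @param x a [sampled_signal()].
#' @return numeric vector of times in seconds, one per sample.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' @export
print.sampled_signal <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<sampled_signal '%s': %d samples @ %g Hz, t0 = %g s, %.1f s>\n",
              x$label, n, x$fs, x$t0, n / x$fs))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

# replace the values of a signal, keeping timeline metadata
signal_with <- function(x, values, label = x$label) {
  sampled_signal(values, x$fs, x$t0, label)
}

# frame index (1-based) of a time point on a signal's grid; floor convention so
# a half-open interval [start, end) covers frames floor(start*fs)..floor(end*fs)-1
time_to_frame <- function(t, fs, t0 = 0) floor((t - t0) * fs + 1e-9) + 1L

#' Linearly resample a signal to a new rate
#'
#' Plain linear interpolation onto a uniform grid at `fs_new`, spanning the
#' same time extent. Used to place streams on the shared 64 Hz timeline and to
#' decimate RR tracks to 4 Hz for spectral analysis.
#'
#' @param x a [sampled_signal()].
#' @param fs_new target sampling rate (Hz).
#' @return a [sampled_signal()] at `fs_new`.
#' @export
resample_signal <- function(x, fs_new) {
  stopifnot(inherits(x, "sampled_signal"), fs_new > 0)
  if (abs(fs_new - x$fs) < 1e-12) return(x)
  t_old <- signal_times(x)
  n_new <- max(2L, floor(length(x$values) * fs_new / x$fs))
  t_new <- x$t0 + (seq_len(n_new) - 1) / fs_new
  v <- approx(t_old, x$values, xout = t_new, rule = 2)$y
  sampled_signal(v, fs_new, x$t0, x$label)
}

# population (1/n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# z-normalize with population SD so that the unbiased autocorrelation at lag 0
# equals exactly one
znorm_pop <- function(x) {
  s <- sd_pop(x)
  if (s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x)) / s
}

# remove a least-squares straight line
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) return(x - mean(x))
  t <- seq_len(n)
  unname(residuals(lm(x ~ t)))
}
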