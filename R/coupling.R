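#' Unbiased lagged cross-correlation of two equal-length series
#'
#' Both series are linearly detrended and z-normalized with the population
#' SD, so the same pipeline applied to `(x, x)` gives an autocorrelation of
#' exactly 1 at zero lag. The unbiased estimator
#' `r(k) = (1/(N - |k|)) sum_t x(t) y(t + k)` is evaluated for
#' `k = -max_lag..max_lag`; positive `k` means `x` leads `y` (`y` echoes `x`
#' later).
#'
#' @param x,y numeric vectors of equal length `N >= 2 * max_lag`.
#' @param max_lag maximum lag in samples.
#' @return list of class `xcorr_curve`: `curve` (data.frame `lag`, `r`),
#'   `n`, `max_lag`, `degenerate` (`TRUE` with an all-`NA` curve when either
#'   input has zero variance).
#' @export
xcorr_unbiased <- function(x, y, max_lag) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  N <- length(x)
  max_lag <- as.integer(max_lag)
  stopifnot(N >= 2L * max_lag, max_lag >= 1L)
  ks <- -max_lag:max_lag
  # degenerate when the raw series is (numerically) constant or exactly linear
  degen <- function(v, d) {
    sd_pop(v) <= 1e-12 * max(1, abs(mean(v))) ||
      sd_pop(d) <= 1e-10 * max(sd_pop(v), 1e-300)
  }
  xd <- detrend_linear(x); yd <- detrend_linear(y)
  xt <- if (degen(x, xd)) rep(NA_real_, N) else znorm_pop(xd)
  yt <- if (degen(y, yd)) rep(NA_real_, N) else znorm_pop(yd)
  if (anyNA(xt) || anyNA(yt)) {
    return(structure(list(curve = data.frame(lag = ks, r = NA_real_),
                          n = N, max_lag = max_lag, degenerate = TRUE),
                     class = "xcorr_curve"))
  }
  r <- vapply(ks, function(k) {
    if (k >= 0) sum(xt[1:(N - k)] * yt[(1 + k):N]) / (N - k)
    else sum(xt[(1 - k):N] * yt[1:(N + k)]) / (N + k)
  }, 1.0)
  # the unbiased scaling can marginally exceed |1| on strongly periodic
  # segments; clip so correlations stay interpretable on the [-1, 1] scale
  # and exact ties resolve by the stated lag tie-breaks
  r <- pmin(1, pmax(-1, r))
  structure(list(curve = data.frame(lag = ks, r = r),
                 n = N, max_lag = max_lag, degenerate = FALSE),
            class = "xcorr_curve")
}

#' Peak extraction and directionality classification
#'
#' The peak is the lag maximizing `|r(k)|`; the signed correlation at that
#' lag is reported. Ties in `|r|` are broken toward smaller `|k|`, then
#' toward negative `k`. The lag class is `POS`/`NEG`/`ZERO` by the sign of
#' the peak lag (`ZERO` is excluded from lag-directionality contrasts); the
#' correlation class is `POS`/`NEG` by the sign of the peak correlation.
#'
#' @param xc an `xcorr_curve` from [xcorr_unbiased()], or a data.frame with
#'   columns `lag`, `r`.
#' @param fs sampling rate used to convert the lag to seconds (default 1,
#'   i.e. the lag is reported in samples only).
#' @return list `lag_samples`, `lag_s`, `r_peak`, `lag_class`, `corr_class`
#'   (all `NA` for a degenerate curve).
#' @export
peak_and_classify <- function(xc, fs = 1) {
  curve <- if (inherits(xc, "xcorr_curve")) xc$curve else xc
  if (all(is.na(curve$r))) {
    return(list(lag_samples = NA_integer_, lag_s = NA_real_, r_peak = NA_real_,
                lag_class = NA_character_, corr_class = NA_character_))
  }
  ord <- order(-abs(curve$r), abs(curve$lag), curve$lag)
  best <- ord[1]
  k <- curve$lag[best]
  r <- curve$r[best]
  list(lag_samples = as.integer(k), lag_s = k / fs, r_peak = r,
       lag_class = if (k > 0) "POS" else if (k < 0) "NEG" else "ZERO",
       corr_class = if (r >= 0) "POS" else "NEG")
}

#' Per-segment coupling analysis of a session
#'
#' For each kept segment, the two participants' tracks restricted to the
#' segment are cross-correlated ([xcorr_unbiased()]) and the peak lag and
#' correlation are classified ([peak_and_classify()]). The first participant
#' of `tracks` is the reference: a positive lag means that participant led.
#' The lag range never exceeds a quarter of the segment length (the unbiased
#' estimator's variance grows as the overlap shrinks, so wider searches on
#' short segments produce spurious boundary peaks); segments where this cap
#' shrinks the requested `max_lag` are flagged in the output.
#'
#' @param tracks named list of two [sampled_signal()]s on a shared timeline
#'   (e.g. the interpolated RR tracks; speech intensity or pitch work the
#'   same way).
#' @param segments data.frame from [segment_phases()].
#' @param signal_kind label stored in the output (default `"rr"`).
#' @param max_lag maximum lag in seconds (default 5).
#' @param phases segment phases to analyse (default simultaneous and
#'   both-speaking, the conversational exchange phases).
#' @return data.frame `(segment_id, phase, signal_kind, reference, n,
#'   max_lag_s, shrunk, lag_samples, lag_s, r_peak, lag_class, corr_class)`,
#'   one row per analysed segment; the full curves are kept in attribute
#'   `curves` (a list keyed by segment id).
#' @export
couple_session <- function(tracks, segments, signal_kind = "rr", max_lag = 5,
                           phases = c("simultaneous", "both_speaking")) {
  stopifnot(length(tracks) == 2L)
  fs <- tracks[[1]]$fs
  stopifnot(abs(fs - tracks[[2]]$fs) < 1e-9)
  if (is.null(names(tracks))) names(tracks) <- c("p1", "p2")
  ref <- names(tracks)[1]
  seg <- segments[segments$kept & segments$phase %in% phases, , drop = FALSE]
  curves <- list()
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    lo <- time_to_frame(seg$t_start[i], fs, tracks[[1]]$t0)
    hi <- time_to_frame(seg$t_end[i], fs, tracks[[1]]$t0) - 1L
    hi <- min(hi, length(tracks[[1]]$values), length(tracks[[2]]$values))
    n <- hi - lo + 1L
    if (n < 8L) return(NULL)
    K <- round(max_lag * fs)
    shrunk <- FALSE
    if (n < 4L * K) {
      K <- max(1L, n %/% 4L)
      shrunk <- TRUE
    }
    xc <- xcorr_unbiased(tracks[[1]]$values[lo:hi], tracks[[2]]$values[lo:hi], K)
    pk <- peak_and_classify(xc, fs)
    curves[[as.character(seg$segment_id[i])]] <<- xc$curve
    data.frame(segment_id = seg$segment_id[i], phase = seg$phase[i],
               signal_kind = signal_kind, reference = ref, n = n,
               max_lag_s = K / fs, shrunk = shrunk,
               lag_samples = pk$lag_samples, lag_s = pk$lag_s,
               r_peak = pk$r_peak,
               lag_class = pk$lag_class %||% NA_character_,
               corr_class = pk$corr_class %||% NA_character_)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(segment_id = integer(), phase = character(),
               signal_kind = character(), reference = character(),
               n = integer(), max_lag_s = numeric(), shrunk = logical(),
               lag_samples = integer(), lag_s = numeric(), r_peak = numeric(),
               lag_class = character(), corr_class = character())
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}

# negate a lag class (participant-swap antisymmetry)
flip_lag_class <- function(cls) {
  ifelse(cls == "POS", "NEG", ifelse(cls == "NEG", "POS", cls))
}
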