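#' Global histogram bin edges for a recording
#'
#' Entropies are computed against one fixed 10-bin histogram per recording so
#' windowed values are comparable across the session.
#'
#' @param x numeric vector (the whole recording).
#' @param bins number of bins (default 10).
#' @return numeric vector of `bins + 1` strictly increasing edges spanning
#'   the recording's range (degenerate ranges are widened symmetrically).
#' @export
global_bin_edges <- function(x, bins = 10) {
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
  seq(lo, hi, length.out = bins + 1L)
}

bin_probs <- function(window, edges) {
  window <- window[is.finite(window)]
  window <- pmin(pmax(window, edges[1]), edges[length(edges)])
  cnt <- tabulate(pmin(length(edges) - 1L,
                       findInterval(window, edges, rightmost.closed = TRUE)),
                  nbins = length(edges) - 1L)
  cnt / sum(cnt)
}

#' Shannon entropy of a window against global bins
#'
#' `H = -sum p_i ln p_i` over the global histogram bins (natural log); empty
#' bins contribute nothing.
#'
#' @param window numeric vector.
#' @param edges bin edges from [global_bin_edges()].
#' @return entropy in nats, in `[0, ln(bins)]`.
#' @export
shannon_entropy <- function(window, edges) {
  p <- bin_probs(window, edges)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Renyi entropy of a window against global bins
#'
#' `H_a = ln(sum p_i^a) / (1 - a)` over occupied bins; `a = 1` returns the
#' Shannon limit. Negative orders emphasize rare events, positive orders
#' frequent ones.
#'
#' @param window numeric vector.
#' @param edges bin edges from [global_bin_edges()].
#' @param alpha entropy order (the study grid is -5, -3, -1, 1, 3, 5).
#' @return entropy in nats.
#' @export
renyi_entropy <- function(window, edges, alpha) {
  if (alpha == 1) return(shannon_entropy(window, edges))
  p <- bin_probs(window, edges)
  p <- p[p > 0]
  log(sum(p^alpha)) / (1 - alpha)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A/B)` where `B` counts pairs of distinct length-`m`
#' templates within Chebyshev tolerance `r = r_frac * SD(window)` and `A` the
#' same for length `m + 1` (templates `i = 1..n-m` for both, self-matches
#' excluded).
#'
#' @param x numeric window.
#' @param m template length (default 2).
#' @param r_frac tolerance as a fraction of the window SD (default 0.2).
#' @return sample entropy (dimensionless); `NA` for degenerate windows
#'   (zero SD) or when no template pair matches (`A = 0` or `B = 0`).
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.2) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1L) return(NA_real_)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  r <- r_frac * s
  nt <- n - m
  D <- abs(outer(x, x, "-"))
  Dm <- D[seq_len(nt), seq_len(nt)]
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      Dm <- pmax(Dm, D[seq_len(nt) + k, seq_len(nt) + k])
    }
  }
  B <- (sum(Dm <= r) - nt) / 2
  Dm1 <- pmax(Dm, D[seq_len(nt) + m, seq_len(nt) + m])
  A <- (sum(Dm1 <= r) - nt) / 2
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

#' Coarse-grain a series by block averaging
#'
#' Non-overlapping blocks of `scale` samples are averaged; the remainder is
#' dropped.
#'
#' @param x numeric vector, length at least `scale`.
#' @param scale block length (the multiscale grid is 4, 8, 16, 32, 128).
#' @return numeric vector of length `floor(length(x) / scale)`.
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  if (length(x) < scale) stop("series shorter than coarse-graining scale")
  if (scale == 1L) return(as.numeric(x))
  nb <- length(x) %/% scale
  colMeans(matrix(x[seq_len(nb * scale)], nrow = scale))
}

#' Diffusion entropy analysis
#'
#' The series is reduced to an event sequence (`1` where the value lies
#' outside the +/- `stripe` SD stripe around the series median), diffusion
#' trajectories are built as moving-window event counts, and for each window
#' length `l` on a dyadic grid the entropy `S(l)` of the displacement
#' distribution is estimated with a Freedman-Diaconis histogram, as the
#' differential form `-sum p_i ln p_i + ln(bin width)` (the bin-width term
#' keeps `S(l)` on the absolute displacement scale; since displacements are
#' integer event counts the bin width is floored at 1). The scaling
#' exponent `delta` is the least-squares slope of `S(l)` against `ln l`
#' inside `fit_range`, capped at 1; the complexity index is
#' `mu_r = 1 + 1/delta`.
#'
#' The default fit range is `[10, max(32, n/100)]`: above `n/100` the
#' overlapping diffusion windows leave too few independent displacement
#' samples and the empirical entropy is biased downward. The range was
#' validated against the two analytic anchors (`delta = 0.5` for i.i.d.
#' series, `delta -> 1` for ballistic/persistent series).
#'
#' @param x numeric series, length >= 256.
#' @param stripe stripe half-width in SD units (default 1).
#' @param fit_range numeric `c(l_min, l_max)`; default
#'   `c(10, max(32, length(x)/100))`.
#' @param min_events minimum number of events for a defined result.
#' @return list of class `dea_result`: `delta` (capped), `delta_raw`,
#'   `mu_r`, `entropy_curve` (data.frame `l`, `S`), `fit_range`, `n_events`.
#'   All-`NA` (flagged missing) when fewer than `min_events` events occur.
#' @export
dea <- function(x, stripe = 1, fit_range = NULL, min_events = 10) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 256L) stop("dea needs at least 256 samples")
  if (is.null(fit_range)) fit_range <- c(10, max(32, n / 100))
  s <- sd(x)
  eps <- if (is.finite(s) && s > 0) {
    as.integer(abs(x - median(x)) > stripe * s)
  } else integer(n)
  missing_result <- structure(
    list(delta = NA_real_, delta_raw = NA_real_, mu_r = NA_real_,
         entropy_curve = data.frame(l = numeric(), S = numeric()),
         fit_range = fit_range, n_events = sum(eps)),
    class = "dea_result")
  if (sum(eps) < min_events) return(missing_result)

  cs <- c(0, cumsum(eps))
  lgrid <- unique(round(2^seq(log2(4), log2(n / 4), by = 0.5)))
  S <- vapply(lgrid, function(l) {
    disp <- cs[(1 + l):(n + 1)] - cs[1:(n + 1 - l)]
    h <- max(1, 2 * stats::IQR(disp) / length(disp)^(1 / 3))  # FD, floored at 1
    breaks <- seq(min(disp) - h / 2, max(disp) + h, by = h)
    cnt <- graphics::hist(disp, breaks = breaks, plot = FALSE)$counts
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log(p)) + log(h)
  }, 1.0)
  curve <- data.frame(l = lgrid, S = S)
  fit_idx <- which(lgrid >= fit_range[1] & lgrid <= fit_range[2] & is.finite(S))
  if (length(fit_idx) < 3L) return(missing_result)
  slope <- unname(coef(lm(S[fit_idx] ~ log(lgrid[fit_idx])))[2])
  delta <- min(1, slope)
  structure(list(delta = delta, delta_raw = slope,
                 mu_r = mu_from_delta(delta), entropy_curve = curve,
                 fit_range = fit_range, n_events = sum(eps)),
            class = "dea_result")
}

#' @export
print.dea_result <- function(x, ...) {
  cat(sprintf("<dea_result: delta = %.3f (raw %.3f), mu_r = %.3f, %d events>\n",
              x$delta, x$delta_raw, x$mu_r, x$n_events))
  invisible(x)
}

#' Multiscale diffusion entropy analysis
#'
#' Runs [dea()] on the series and on its block-averaged coarse-grained
#' representations at the dyadic scales.
#'
#' @param x numeric series.
#' @param scales coarse-graining factors; scale 1 is the raw series.
#' @param ... passed to [dea()].
#' @return data.frame `(scale, delta, mu_r, n_events)`; scales whose
#'   coarse-grained series is shorter than 256 samples yield `NA` rows.
#' @export
msdea <- function(x, scales = c(1, 4, 8, 16, 32, 128), ...) {
  rows <- lapply(scales, function(sc) {
    if (length(x) < sc || length(x) %/% sc < 256L) {
      return(data.frame(scale = sc, delta = NA_real_, mu_r = NA_real_,
                        n_events = NA_integer_))
    }
    r <- dea(coarse_grain(x, sc), ...)
    data.frame(scale = sc, delta = r$delta, mu_r = r$mu_r,
               n_events = r$n_events)
  })
  do.call(rbind, rows)
}

#' Complexity index from the diffusion scaling exponent
#'
#' `mu_r = 1 + 1/delta`; the exponent saturates at `delta = 1`, reached for
#' `mu_r >= 2`.
#'
#' @param delta scaling exponent in `(0, 1]`.
#' @return complexity index; `NA` for `delta <= 0`.
#' @export
mu_from_delta <- function(delta) {
  ifelse(is.na(delta) | delta <= 0, NA_real_, 1 + 1 / delta)
}

#' Diffusion scaling exponent from the complexity index
#'
#' Inverse of [mu_from_delta()]: `delta = 1/(mu_r - 1)`, capped at the
#' saturation value 1 (so every `mu_r >= 2` maps to `delta = 1`).
#'
#' @param mu_r complexity index, greater than 1.
#' @return scaling exponent in `(0, 1]`; `NA` for `mu_r <= 1`.
#' @export
delta_from_mu <- function(mu_r) {
  ifelse(is.na(mu_r) | mu_r <= 1, NA_real_, pmin(1, 1 / (mu_r - 1)))
}

#' Sliding-window entropy feature tracks
#'
#' Each requested feature is evaluated on every window `[i, i + win_len)` of
#' the signal; the value is assigned to the window's right edge, so the track
#' is causally aligned with the recording.
#'
#' @param signal a [sampled_signal()].
#' @param win_len window length in samples (default 1000).
#' @param step window step in samples (default 1; larger steps thin the
#'   track).
#' @param features subset of `"shannon"`, `"sampen"`, `"renyi"`.
#' @param alphas Renyi orders (used when `"renyi"` is requested).
#' @param bins global histogram bin count.
#' @param m,r_frac sample-entropy parameters.
#' @param edges optional pre-computed bin edges (default: global edges of
#'   this signal).
#' @return data.frame `(time_s, feature, value)` in long form; zero rows
#'   (with a warning) when the signal is shorter than one window.
#' @export
sliding_features <- function(signal, win_len = 1000, step = 1,
                             features = c("shannon", "sampen"),
                             alphas = c(-5, -3, -1, 1, 3, 5), bins = 10,
                             m = 2, r_frac = 0.2, edges = NULL) {
  stopifnot(inherits(signal, "sampled_signal"))
  features <- match.arg(features, c("shannon", "sampen", "renyi"),
                        several.ok = TRUE)
  v <- signal$values
  n <- length(v)
  if (n < win_len) {
    warning("sliding_features: signal shorter than one window; empty track")
    return(data.frame(time_s = numeric(), feature = character(),
                      value = numeric()))
  }
  if (is.null(edges)) edges <- global_bin_edges(v, bins)
  starts <- seq(1L, n - win_len + 1L, by = step)
  t_right <- signal$t0 + (starts + win_len - 2L) / signal$fs
  rows <- list()
  for (f in features) {
    if (f == "renyi") {
      for (a in alphas) {
        vals <- vapply(starts, function(s)
          renyi_entropy(v[s:(s + win_len - 1L)], edges, a), 1.0)
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = t_right, feature = sprintf("renyi_%g", a), value = vals)
      }
    } else {
      fn <- switch(f,
                   shannon = function(w) shannon_entropy(w, edges),
                   sampen = function(w) sample_entropy(w, m, r_frac))
      vals <- vapply(starts, function(s) fn(v[s:(s + win_len - 1L)]), 1.0)
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = t_right, feature = f, value = vals)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
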