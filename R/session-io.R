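#' @name session_io
#' @title Session input/output
#'
#' @description
#' Readers and writers for the per-dyad session layout: one E4-style PPG CSV
#' per participant (optional two-line header carrying an absolute start
#' timestamp and the sampling rate, then one sample per line), a speaking
#' annotation CSV (`participant_id, start_s, end_s`), an emotion annotation CSV
#' (`time_s, perspective, arousal, valence`, one row per 5-second slot), and
#' optional pitch/intensity tracks. All streams are placed on a shared 64 Hz
#' timeline with time expressed in relative seconds from session start;
#' absolute epoch timestamps are converted on read.
NULL

SYNTH_EPOCH <- 1.6e9  # epoch base used when writing E4-style headers

read_numeric_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  raw_n <- length(lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  bad <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  dropped <- (raw_n - length(vals))
  list(values = vals, dropped = dropped)
}

#' Read an E4-style single-column PPG CSV
#'
#' The file holds one numeric sample per line. If the first line is an
#' epoch-like timestamp (> 1e6), the first two lines are interpreted as the
#' recording start time and the sampling rate (the Empatica E4 export dialect);
#' a rate that disagrees with `fs_expected` is a hard error. Blank or
#' non-numeric lines are dropped with a warning giving the count.
#'
#' @param path file path.
#' @param fs_expected expected sampling rate in Hz (default 64).
#' @return a [sampled_signal()] at `fs_expected`, `t0 = 0` (relative time);
#'   the absolute start time, when present, is kept in attribute
#'   `start_epoch`.
#' @export
read_ppg_csv <- function(path, fs_expected = 64) {
  parsed <- read_numeric_lines(path)
  vals <- parsed$values
  if (length(vals) == 0L) stop("empty PPG file: ", path)
  start_epoch <- NA_real_
  if (length(vals) >= 2L && vals[1] > 1e6) {
    start_epoch <- vals[1]
    fs_file <- vals[2]
    if (abs(fs_file - fs_expected) > 1e-9) {
      stop(sprintf("PPG header sampling rate %g Hz does not match expected %g Hz (%s)",
                   fs_file, fs_expected, path))
    }
    vals <- vals[-(1:2)]
    if (length(vals) == 0L) stop("PPG file has a header but no samples: ", path)
  }
  if (parsed$dropped > 0L) {
    warning(sprintf("read_ppg_csv: dropped %d blank/non-numeric line(s) in %s",
                    parsed$dropped, path))
  }
  sig <- sampled_signal(vals, fs_expected, t0 = 0,
                        label = sub("\\.csv$", "", basename(path)))
  attr(sig, "start_epoch") <- start_epoch
  sig
}

#' Write a signal as an E4-style single-column CSV
#'
#' Values are written at full double precision (`%.17g`) so a write/read
#' round trip is bit-identical.
#'
#' @param sig a [sampled_signal()].
#' @param path output file path.
#' @param header write the two-line (start epoch, fs) header? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(sig, path, header = TRUE) {
  stopifnot(inherits(sig, "sampled_signal"))
  body <- sprintf("%.17g", sig$values)
  if (header) {
    body <- c(sprintf("%.17g", SYNTH_EPOCH + sig$t0), sprintf("%.17g", sig$fs), body)
  }
  writeLines(body, path)
  invisible(path)
}

merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$start_s), , drop = FALSE]
  out_s <- df$start_s[1]; out_e <- df$end_s[1]
  keep_s <- c(); keep_e <- c()
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start_s[i] <= out_e) {
      out_e <- max(out_e, df$end_s[i])
    } else {
      keep_s <- c(keep_s, out_s); keep_e <- c(keep_e, out_e)
      out_s <- df$start_s[i]; out_e <- df$end_s[i]
    }
  }
  keep_s <- c(keep_s, out_s); keep_e <- c(keep_e, out_e)
  data.frame(start_s = keep_s, end_s = keep_e)
}

#' Read speaker-attributed speech segment annotations
#'
#' Rows are `(participant_id, start_s, end_s)`. Rows with `end_s <= start_s`
#' are rejected with a warning; intervals are clipped to `[0, session_len]`
#' and overlapping or touching intervals of the same participant are merged.
#'
#' @param path CSV file with columns `participant_id, start_s, end_s`.
#' @param session_len session length in seconds used for clipping.
#' @param participants optional character vector of known participant ids; an
#'   id outside this set is a hard error.
#' @return data.frame `(participant_id, start_s, end_s)` of merged, clipped
#'   intervals, ordered by participant then start time.
#' @export
read_speech_annotations <- function(path, session_len, participants = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop("speech annotation file must have columns: ", paste(need, collapse = ", "))
  }
  df$participant_id <- as.character(df$participant_id)
  if (!is.null(participants)) {
    unknown <- setdiff(unique(df$participant_id), participants)
    if (length(unknown) > 0L) {
      stop("unknown participant id(s) in ", path, ": ", paste(unknown, collapse = ", "))
    }
  }
  bad <- df$end_s <= df$start_s
  if (any(bad)) {
    warning(sprintf("read_speech_annotations: rejected %d row(s) with end <= start",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  df$start_s <- pmax(0, df$start_s)
  df$end_s <- pmin(session_len, df$end_s)
  df <- df[df$end_s > df$start_s, , drop = FALSE]
  out <- do.call(rbind, lapply(split(df, df$participant_id), function(d) {
    m <- merge_intervals(d[, c("start_s", "end_s")])
    data.frame(participant_id = d$participant_id[1], m)
  }))
  rownames(out) <- NULL
  out
}

#' Rasterize intervals to a binary speaking mask
#'
#' Frame `i` (0-based) is 1 iff its time `t0 + i/fs` falls inside some
#' half-open interval `[start_s, end_s)`.
#'
#' @param intervals data.frame with columns `start_s`, `end_s` (seconds).
#' @param fs sampling rate (Hz).
#' @param n number of frames of the output mask.
#' @param t0 time of the first frame (s).
#' @return binary [sampled_signal()] of length `n`.
#' @export
intervals_to_mask <- function(intervals, fs, n, t0 = 0) {
  mask <- integer(n)
  if (!is.null(intervals) && nrow(intervals) > 0L) {
    for (i in seq_len(nrow(intervals))) {
      lo <- ceiling((intervals$start_s[i] - t0) * fs - 1e-9) + 1
      hi <- ceiling((intervals$end_s[i] - t0) * fs - 1e-9)
      lo <- max(1L, as.integer(lo)); hi <- min(n, as.integer(hi))
      if (hi >= lo) mask[lo:hi] <- 1L
    }
  }
  sampled_signal(mask, fs, t0, "speak_mask")
}

#' Recover the merged interval set from a binary mask
#'
#' Inverse of [intervals_to_mask()]: each maximal run of ones becomes one
#' half-open interval on the frame grid.
#'
#' @param mask binary [sampled_signal()].
#' @return data.frame `(start_s, end_s)`.
#' @export
mask_to_intervals <- function(mask) {
  stopifnot(inherits(mask, "sampled_signal"))
  r <- rle(as.integer(mask$values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- r$values == 1L
  data.frame(start_s = mask$t0 + (starts[on] - 1) / mask$fs,
             end_s = mask$t0 + ends[on] / mask$fs)
}

#' Per-perspective emotion annotation track
#'
#' Holds the 5-second labels and their frame-level expansion on the 64 Hz
#' timeline (each label repeated `5 * fs` times).
#'
#' @param perspective one of `"self"`, `"partner"`, `"external"`.
#' @param dimension one of `"arousal"`, `"valence"`.
#' @param labels5s integer labels in 1..5, one per 5-second slot.
#' @param fs frame rate for expansion (default 64 Hz).
#' @param n target frame count; the expansion is truncated, or padded with the
#'   last label (with a warning), to exactly `n` frames.
#' @return an object of class `emotion_track`.
#' @export
emotion_track <- function(perspective, dimension, labels5s, fs = 64, n = NULL) {
  perspective <- match.arg(perspective, c("self", "partner", "external"))
  dimension <- match.arg(dimension, c("arousal", "valence"))
  labels5s <- as.integer(labels5s)
  if (any(is.na(labels5s)) || any(labels5s < 1L | labels5s > 5L)) {
    stop("emotion labels must be integers in 1..5")
  }
  if (is.null(n)) n <- length(labels5s) * 5L * fs
  labels64 <- expand_emotion(labels5s, fs, n)
  structure(list(perspective = perspective, dimension = dimension,
                 labels5s = labels5s, labels64 = labels64, fs = fs),
            class = "emotion_track")
}

#' Expand 5-second emotion labels to frame level
#'
#' Each label is repeated across its 5-second slot (`5 * fs` frames). The
#' result is truncated to `n` frames; if the labels do not cover the session,
#' the tail is padded with the final label and a warning is raised.
#'
#' @param labels5s integer labels in 1..5.
#' @param fs frame rate (Hz).
#' @param n target number of frames.
#' @return integer vector of length `n`.
#' @export
expand_emotion <- function(labels5s, fs = 64, n) {
  labels5s <- as.integer(labels5s)
  if (any(is.na(labels5s)) || any(labels5s < 1L | labels5s > 5L)) {
    stop("emotion labels must be integers in 1..5")
  }
  per <- as.integer(round(5 * fs))
  full <- rep(labels5s, each = per)
  if (length(full) < n) {
    warning(sprintf("expand_emotion: padded %d frame(s) with the last label",
                    n - length(full)))
    full <- c(full, rep(labels5s[length(labels5s)], n - length(full)))
  }
  full[seq_len(n)]
}

#' Bundle of all aligned streams of one dyadic session
#'
#' @param ppg named list (by participant id) of PPG [sampled_signal()]s.
#' @param speak_mask named list of binary [sampled_signal()]s.
#' @param intensity named list of [sampled_signal()]s (may be `NULL`).
#' @param pitch named list of pitch [sampled_signal()]s (may be `NULL`).
#' @param emotion list of [emotion_track()]s.
#' @param meta list with at least `participants` (length 2) and `fs`.
#' @return an object of class `session_bundle`.
#' @export
session_bundle <- function(ppg, speak_mask, intensity = NULL, pitch = NULL,
                           emotion = list(), meta = list()) {
  stopifnot(length(meta$participants) == 2L)
  fs <- meta$fs %||% 64
  for (s in c(ppg, speak_mask, intensity, pitch)) {
    if (!is.null(s) && abs(s$fs - fs) > 1e-9) {
      stop("all session streams must share fs = ", fs, " Hz")
    }
  }
  for (m in speak_mask) {
    if (!all(m$values %in% c(0, 1))) stop("speak masks must be binary")
  }
  structure(list(ppg = ppg, speak_mask = speak_mask, intensity = intensity,
                 pitch = pitch, emotion = emotion, meta = meta),
            class = "session_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle: participants %s, fs %g Hz, %.0f s, %d emotion track(s)>\n",
              paste(x$meta$participants, collapse = "/"), x$meta$fs,
              length(x$ppg[[1]]$values) / x$meta$fs, length(x$emotion)))
  invisible(x)
}

#' Write a session bundle to a directory
#'
#' Produces the exact plain-text layout [read_session()] consumes:
#' `ppg_<pid>.csv`, `intensity_<pid>.csv`, `pitch_<pid>.csv` (E4-style single
#' column), `speech_annotations.csv`, `emotions.csv` and `meta.yaml`.
#'
#' @param bundle a [session_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pids <- bundle$meta$participants
  for (pid in pids) {
    write_ppg_csv(bundle$ppg[[pid]], file.path(dir, paste0("ppg_", pid, ".csv")))
    if (!is.null(bundle$intensity)) {
      write_ppg_csv(bundle$intensity[[pid]],
                    file.path(dir, paste0("intensity_", pid, ".csv")))
    }
    if (!is.null(bundle$pitch)) {
      write_ppg_csv(bundle$pitch[[pid]],
                    file.path(dir, paste0("pitch_", pid, ".csv")))
    }
  }
  ann <- do.call(rbind, lapply(pids, function(pid) {
    iv <- mask_to_intervals(bundle$speak_mask[[pid]])
    if (nrow(iv) == 0L) return(NULL)
    data.frame(participant_id = pid, iv)
  }))
  if (is.null(ann)) ann <- data.frame(participant_id = character(),
                                      start_s = numeric(), end_s = numeric())
  write.csv(ann, file.path(dir, "speech_annotations.csv"), row.names = FALSE)

  if (length(bundle$emotion) > 0L) {
    emo <- NULL
    for (persp in unique(vapply(bundle$emotion, `[[`, "", "perspective"))) {
      tr_a <- find_emotion_track(bundle$emotion, persp, "arousal")
      tr_v <- find_emotion_track(bundle$emotion, persp, "valence")
      k <- max(length(tr_a$labels5s), length(tr_v$labels5s))
      emo <- rbind(emo, data.frame(
        time_s = 5 * (seq_len(k) - 1), perspective = persp,
        arousal = tr_a$labels5s[seq_len(k)], valence = tr_v$labels5s[seq_len(k)]))
    }
    write.csv(emo, file.path(dir, "emotions.csv"), row.names = FALSE)
  }
  yaml::write_yaml(list(participants = as.list(pids), fs = bundle$meta$fs,
                        duration_s = length(bundle$ppg[[1]]$values) / bundle$meta$fs),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Find an emotion track by perspective and dimension
#'
#' @param tracks list of [emotion_track()]s.
#' @param perspective,dimension the combination to look up.
#' @return the matching [emotion_track()], or `NULL`.
#' @export
find_emotion_track <- function(tracks, perspective, dimension) {
  for (tr in tracks) {
    if (tr$perspective == perspective && tr$dimension == dimension) return(tr)
  }
  NULL
}

#' Read a session bundle from a directory
#'
#' @param dir directory written by [write_session()] (or laid out the same
#'   way by hand).
#' @param fs_expected expected sampling rate (Hz).
#' @return a [session_bundle()].
#' @export
read_session <- function(dir, fs_expected = 64) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  pids <- unlist(meta$participants)
  ppg <- lapply(pids, function(pid)
    read_ppg_csv(file.path(dir, paste0("ppg_", pid, ".csv")), fs_expected))
  names(ppg) <- pids
  n <- length(ppg[[1]]$values)
  dur <- n / fs_expected

  ann <- read_speech_annotations(file.path(dir, "speech_annotations.csv"),
                                 session_len = dur, participants = pids)
  speak_mask <- lapply(pids, function(pid)
    intervals_to_mask(ann[ann$participant_id == pid, , drop = FALSE],
                      fs_expected, n))
  names(speak_mask) <- pids

  read_opt <- function(prefix) {
    paths <- file.path(dir, paste0(prefix, "_", pids, ".csv"))
    if (!all(file.exists(paths))) return(NULL)
    out <- lapply(paths, read_ppg_csv, fs_expected = fs_expected)
    names(out) <- pids
    out
  }
  intensity <- read_opt("intensity")
  pitch <- read_opt("pitch")

  emotion <- list()
  emo_path <- file.path(dir, "emotions.csv")
  if (file.exists(emo_path)) {
    emo <- read.csv(emo_path, stringsAsFactors = FALSE)
    for (persp in unique(emo$perspective)) {
      d <- emo[emo$perspective == persp, , drop = FALSE]
      d <- d[order(d$time_s), , drop = FALSE]
      for (dim in c("arousal", "valence")) {
        emotion[[length(emotion) + 1L]] <-
          emotion_track(persp, dim, d[[dim]], fs_expected, n)
      }
    }
  }
  session_bundle(ppg, speak_mask, intensity, pitch, emotion,
                 meta = list(participants = pids, fs = fs_expected))
}
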