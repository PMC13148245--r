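#' Segment a session into speak-listen phases
#'
#' The two binary speaking masks define a frame-wise state: one participant
#' speaks while the other listens (simultaneous speak-listen, in either
#' role), both speak, or both listen. Maximal runs of each state become
#' candidate segments; runs shorter than `min_len` are absorbed into the
#' neighbouring run with the longer duration (majority vote) until every run
#' meets the minimum. Simultaneous segments whose original speak-listen
#' purity falls below `purity_min` (backchannel-heavy stretches) are flagged
#' `kept = FALSE` and excluded from analysis but retained in the table so the
#' segments cover the session exactly.
#'
#' @param maskA,maskB binary speaking [sampled_signal()]s on a shared
#'   timeline.
#' @param min_len minimum segment length in seconds (default 5, one emotion
#'   annotation period).
#' @param purity_min minimum fraction of frames with speaker mask 1 and
#'   listener mask 0 for a simultaneous segment (default 0.9).
#' @param ids participant ids, length 2 (default `c("p1", "p2")`).
#' @return data.frame `(segment_id, phase, t_start, t_end, speaker_id,
#'   listener_id, purity, kept)` with phases `"simultaneous"`,
#'   `"both_speaking"`, `"both_listening"`; half-open `[t_start, t_end)`
#'   intervals, non-overlapping and ordered.
#' @export
segment_phases <- function(maskA, maskB, min_len = 5, purity_min = 0.9,
                           ids = c("p1", "p2")) {
  stopifnot(inherits(maskA, "sampled_signal"), inherits(maskB, "sampled_signal"),
            abs(maskA$fs - maskB$fs) < 1e-9)
  fs <- maskA$fs
  a <- as.integer(maskA$values != 0)
  b <- as.integer(maskB$values != 0)
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  if (all(a == 0) && all(b == 0)) {
    warning("segment_phases: both masks all-zero; only both_listening segments")
  }
  # states: 1 = A speaks/B listens, 2 = B speaks/A listens, 3 = both, 4 = neither
  state <- ifelse(a == 1 & b == 0, 1L,
                  ifelse(b == 1 & a == 0, 2L, ifelse(a == 1, 3L, 4L)))
  min_frames <- max(1L, round(min_len * fs))
  repeat {
    r <- rle(state)
    if (length(r$lengths) <= 1L || min(r$lengths) >= min_frames) break
    i <- which.min(r$lengths)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    left_len <- if (i > 1L) r$lengths[i - 1L] else -1L
    right_len <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    new_val <- if (left_len >= right_len) r$values[i - 1L] else r$values[i + 1L]
    state[starts[i]:ends[i]] <- new_val
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  phase_names <- c("simultaneous", "simultaneous", "both_speaking", "both_listening")
  rows <- lapply(seq_along(r$values), function(i) {
    st <- r$values[i]
    idx <- starts[i]:ends[i]
    speaker <- if (st == 1L) ids[1] else if (st == 2L) ids[2] else NA_character_
    listener <- if (st == 1L) ids[2] else if (st == 2L) ids[1] else NA_character_
    purity <- if (st == 1L) mean(a[idx] == 1 & b[idx] == 0)
    else if (st == 2L) mean(b[idx] == 1 & a[idx] == 0)
    else NA_real_
    data.frame(phase = phase_names[st],
               t_start = (starts[i] - 1L) / fs, t_end = ends[i] / fs,
               speaker_id = speaker, listener_id = listener,
               purity = purity,
               kept = is.na(purity) || purity >= purity_min)
  })
  out <- do.call(rbind, rows)
  out <- cbind(segment_id = seq_len(nrow(out)), out)
  out$t_start <- out$t_start + maskA$t0
  out$t_end <- out$t_end + maskA$t0
  rownames(out) <- NULL
  out
}

#' Within-participant speaking/listening interval pairs
#'
#' For each participant, consecutive (own-speaking, own-listening) intervals
#' from the simultaneous segments are paired in time order and trimmed to
#' the shorter of the two so the pair is length-comparable.
#'
#' @param segments data.frame from [segment_phases()].
#' @return data.frame `(participant_id, speak_start, speak_end, listen_start,
#'   listen_end)`; a participant who never listens contributes no rows (with
#'   a warning).
#' @export
within_participant_pairs <- function(segments) {
  seg <- segments[segments$phase == "simultaneous" & segments$kept, , drop = FALSE]
  pids <- unique(c(seg$speaker_id, seg$listener_id))
  pids <- pids[!is.na(pids)]
  rows <- list()
  for (pid in pids) {
    own <- seg[seg$speaker_id == pid | seg$listener_id == pid, , drop = FALSE]
    own <- own[order(own$t_start), , drop = FALSE]
    role <- ifelse(own$speaker_id == pid, "speak", "listen")
    if (!any(role == "listen")) {
      warning("within_participant_pairs: participant ", pid, " never listens")
      next
    }
    i <- 1L
    while (i < nrow(own)) {
      if (role[i] == "speak" && role[i + 1L] == "listen") {
        len <- min(own$t_end[i] - own$t_start[i],
                   own$t_end[i + 1L] - own$t_start[i + 1L])
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid,
          speak_start = own$t_start[i], speak_end = own$t_start[i] + len,
          listen_start = own$t_start[i + 1L],
          listen_end = own$t_start[i + 1L] + len)
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(participant_id = character(), speak_start = numeric(),
                      speak_end = numeric(), listen_start = numeric(),
                      listen_end = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dominant emotion state of a segment
#'
#' Modal frame-level label over the segment; ties are broken toward the
#' label with the longest contiguous run inside the segment, then toward the
#' earlier-occurring label.
#'
#' @param t_start,t_end segment bounds in seconds (half-open).
#' @param track an [emotion_track()].
#' @return integer state in 1..5, or `NA` if the segment lies outside the
#'   annotated extent.
#' @export
dominant_emotion <- function(t_start, t_end, track) {
  stopifnot(inherits(track, "emotion_track"))
  fs <- track$fs
  lo <- time_to_frame(t_start, fs)
  hi <- time_to_frame(t_end, fs) - 1L
  if (lo < 1L || hi > length(track$labels64) || hi < lo) return(NA_integer_)
  lab <- track$labels64[lo:hi]
  cnt <- tabulate(lab, nbins = 5L)
  top <- which(cnt == max(cnt))
  if (length(top) > 1L) {
    r <- rle(lab)
    longest <- vapply(top, function(s) {
      runs <- r$lengths[r$values == s]
      if (length(runs)) max(runs) else 0L
    }, 1L)
    top <- top[longest == max(longest)]
    if (length(top) > 1L) {
      first_pos <- vapply(top, function(s) match(s, lab), 1L)
      top <- top[which.min(first_pos)]
    }
  }
  as.integer(top[1])
}

#' Attach dominant emotion states to segments
#'
#' Adds one column per perspective x dimension (e.g. `self_arousal`) holding
#' each segment's dominant state.
#'
#' @param segments data.frame from [segment_phases()].
#' @param emotion list of [emotion_track()]s.
#' @return `segments` with the dominant-emotion columns appended.
#' @export
attach_emotions <- function(segments, emotion) {
  for (tr in emotion) {
    col <- paste(tr$perspective, tr$dimension, sep = "_")
    segments[[col]] <- vapply(seq_len(nrow(segments)), function(i)
      dominant_emotion(segments$t_start[i], segments$t_end[i], tr),
      1L)
  }
  segments
}
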