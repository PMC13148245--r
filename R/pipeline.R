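#' Default pipeline configuration
#'
#' One nested list with a block per stage, mirroring the analysis defaults:
#' 0.5-5 Hz 4th-order zero-phase PPG band-pass, 0.4-s minimum peak distance,
#' SDROM window 5 / 20% threshold, 1000-sample feature windows against a
#' 10-bin global histogram, sample entropy m = 2 / r = 0.2, Renyi orders
#' -5..5, dyadic multiscale grid, 5-s minimum segment length, +/- 5 s lag
#' search. `entropy$step` thins the sliding feature track (the windows
#' computed are identical, just fewer of them); per-segment values are means
#' over the windows ending inside the segment.
#'
#' @param ... named overrides, e.g. `pipeline_config(coupling = list(max_lag = 3))`
#'   (merged shallowly per block).
#' @return nested named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ppg = list(low = 0.5, high = 5, order = 4, min_peak_dist = 0.4),
    sdrom = list(window = 5, rel_thresh = 0.2),
    entropy = list(win_len = 1000, step = 64, bins = 10, m = 2, r_frac = 0.2,
                   alphas = c(-5, -3, -1, 1, 3, 5),
                   scales = c(1, 4, 8, 16, 32, 128),
                   stripe = 1),
    hrv = list(seg_len_s = 60),
    segmentation = list(min_len = 5, purity_min = 0.9),
    coupling = list(max_lag = 5),
    pitch = list(min_voiced = 50)
  )
  over <- list(...)
  for (blk in names(over)) {
    if (blk %in% names(cfg) && is.list(over[[blk]])) {
      for (nm in names(over[[blk]])) cfg[[blk]][[nm]] <- over[[blk]][[nm]]
    } else {
      cfg[[blk]] <- over[[blk]]
    }
  }
  cfg
}

#' Cardiopulmonary conditioning of one session
#'
#' Band-pass, peak detection, SDROM cleaning, frame-level RR interpolation
#' and composite respiration for both participants.
#'
#' @param bundle a [session_bundle()].
#' @param config a [pipeline_config()].
#' @return list per participant id: `beats` ([beat_series()]), `rr_track`
#'   ([sampled_signal()]), `respiration` (`respiration_signal`).
#' @export
extract_cardio <- function(bundle, config = pipeline_config()) {
  fs <- bundle$meta$fs
  n <- length(bundle$ppg[[1]]$values)
  out <- lapply(bundle$meta$participants, function(pid) {
    ppg <- bundle$ppg[[pid]]
    bp <- bandpass_ppg(ppg, config$ppg$low, config$ppg$high, config$ppg$order)
    beats <- detect_peaks(bp, config$ppg$min_peak_dist)
    beats <- clean_rr_sdrom(beats, config$sdrom$window, config$sdrom$rel_thresh)
    rr_track <- interpolate_rr(beats, fs, n)
    resp <- derive_respiration(ppg, rr_track)
    list(beats = beats, rr_track = rr_track, respiration = resp)
  })
  names(out) <- bundle$meta$participants
  out
}

# mean of a feature track (time_s, feature, value) within [t_start, t_end)
track_segment_mean <- function(track_df, feature, t_start, t_end) {
  v <- track_df$value[track_df$feature == feature &
                        track_df$time_s >= t_start & track_df$time_s < t_end]
  v <- v[is.finite(v)]
  if (length(v) == 0L) NA_real_ else mean(v)
}

#' Per-segment feature extraction for one session
#'
#' For each kept segment and participant: the HRV panel from the cleaned
#' beats inside the segment (frequency domain only when the segment spans at
#' least `hrv$seg_len_s`), Shannon/sample-entropy means of the sliding RR
#' feature track over the segment, scale-1 diffusion-entropy `delta` and
#' `mu_r` of the segment's RR slice, and pitch window statistics of the
#' gated pitch slice.
#'
#' @param bundle a [session_bundle()].
#' @param cardio result of [extract_cardio()].
#' @param segments data.frame from [segment_phases()].
#' @param config a [pipeline_config()].
#' @return data.frame `(segment_id, participant_id, feature, value)` in long
#'   form.
#' @export
extract_segment_features <- function(bundle, cardio, segments,
                                     config = pipeline_config()) {
  fs <- bundle$meta$fs
  pids <- bundle$meta$participants
  seg <- segments[segments$kept, , drop = FALSE]
  ent_cfg <- config$entropy

  tracks <- lapply(pids, function(pid) {
    sliding_features(cardio[[pid]]$rr_track,
                     win_len = ent_cfg$win_len, step = ent_cfg$step,
                     features = c("shannon", "sampen"), bins = ent_cfg$bins,
                     m = ent_cfg$m, r_frac = ent_cfg$r_frac)
  })
  names(tracks) <- pids

  rows <- list()
  add <- function(sid, pid, feature, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      segment_id = sid, participant_id = pid, feature = feature,
      value = as.numeric(value))
  }
  for (i in seq_len(nrow(seg))) {
    sid <- seg$segment_id[i]
    t0 <- seg$t_start[i]; t1 <- seg$t_end[i]
    for (pid in pids) {
      beats <- cardio[[pid]]$beats
      in_seg <- beats$beat_times >= t0 & beats$beat_times < t1
      rr_seg <- diff(beats$beat_times[in_seg])
      lo <- time_to_frame(t0, fs); hi <- time_to_frame(t1, fs) - 1L
      hi <- min(hi, length(cardio[[pid]]$rr_track$values))
      rr_slice <- cardio[[pid]]$rr_track$values[lo:hi]

      td <- hrv_time_domain(rr_seg)
      pc <- poincare(rr_seg)
      for (nm in names(td)) add(sid, pid, nm, td[[nm]])
      for (nm in names(pc)) add(sid, pid, nm, pc[[nm]])
      if (t1 - t0 >= config$hrv$seg_len_s) {
        fd <- hrv_freq_domain(sampled_signal(rr_slice, fs),
                              seg_len_s = config$hrv$seg_len_s)
        for (nm in c("VLF", "LF", "HF", "LF_norm", "HF_norm", "LF_HF",
                     "total_power")) {
          add(sid, pid, nm, fd[[nm]])
        }
      }
      add(sid, pid, "shannon", track_segment_mean(tracks[[pid]], "shannon", t0, t1))
      add(sid, pid, "sampen", track_segment_mean(tracks[[pid]], "sampen", t0, t1))
      if (length(rr_slice) >= 320L) {
        dd <- dea(rr_slice, stripe = ent_cfg$stripe)
        add(sid, pid, "delta_scale1", dd$delta)
        add(sid, pid, "mu_r_scale1", dd$mu_r)
      }
      if (!is.null(bundle$pitch)) {
        gp <- gate_by_speaker(bundle$pitch[[pid]], bundle$speak_mask[[pid]])
        ps <- pitch_window_stats(gp$values[lo:hi],
                                 min_voiced = config$pitch$min_voiced)
        add(sid, pid, "pitch_mean", ps$mean)
        add(sid, pid, "pitch_sd", ps$sd)
        add(sid, pid, "pitch_skewness", ps$skewness)
        add(sid, pid, "pitch_kurtosis", ps$kurtosis)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

hash_files <- function(paths) {
  paths <- sort(paths[file.exists(paths)])
  h <- tools::md5sum(paths)
  names(h) <- basename(names(h))
  as.list(h)
}

#' Run the full coupling pipeline on one session directory
#'
#' Stages: read session -> cardiopulmonary conditioning -> phase
#' segmentation (+ dominant emotions) -> per-segment features -> per-segment
#' RR coupling -> report tables (feature contrasts and emotion distributions
#' by lag and by correlation directionality). Outputs are tidy CSVs in
#' `out_dir` plus a JSON run manifest with input/output hashes, the config
#' snapshot and per-stage row counts. When `out_dir` already holds a
#' manifest whose input hashes match, the computation is skipped and cached
#' outputs are returned (`manifest$cached = TRUE`).
#'
#' @param session_dir directory readable by [read_session()].
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @return invisible list: `segments`, `features`, `coupling`, `tables`
#'   (named list of the four report tables), `manifest`.
#' @export
run_pipeline <- function(session_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_hash <- hash_files(list.files(session_dir, full.names = TRUE))
  manifest_path <- file.path(out_dir, "run_manifest.json")
  out_files <- c("segments.csv", "features.csv", "coupling.csv",
                 "table1_lag.csv", "table1_corr.csv",
                 "table2_lag.csv", "table2_corr.csv")
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(lapply(old$input_hashes, as.character),
                  lapply(in_hash, as.character)) &&
        all(file.exists(file.path(out_dir, out_files)))) {
      res <- list(
        segments = read.csv(file.path(out_dir, "segments.csv")),
        features = read.csv(file.path(out_dir, "features.csv")),
        coupling = read.csv(file.path(out_dir, "coupling.csv")),
        tables = lapply(c(table1_lag = "table1_lag.csv",
                          table1_corr = "table1_corr.csv",
                          table2_lag = "table2_lag.csv",
                          table2_corr = "table2_corr.csv"),
                        function(f) read.csv(file.path(out_dir, f))),
        manifest = within(old, cached <- TRUE))
      return(invisible(res))
    }
  }

  bundle <- read_session(session_dir)
  cardio <- extract_cardio(bundle, config)
  pids <- bundle$meta$participants
  segments <- segment_phases(bundle$speak_mask[[pids[1]]],
                             bundle$speak_mask[[pids[2]]],
                             min_len = config$segmentation$min_len,
                             purity_min = config$segmentation$purity_min,
                             ids = pids)
  segments <- attach_emotions(segments, bundle$emotion)
  features <- extract_segment_features(bundle, cardio, segments, config)
  rr_tracks <- lapply(cardio, `[[`, "rr_track")
  coupling <- couple_session(rr_tracks, segments, "rr",
                             max_lag = config$coupling$max_lag)
  tables <- list(
    table1_lag = build_contrast_table(features, coupling, "lag", pids),
    table1_corr = build_contrast_table(features, coupling, "correlation", pids),
    table2_lag = build_emotion_table(segments, coupling, "lag"),
    table2_corr = build_emotion_table(segments, coupling, "correlation"))

  write.csv(segments, file.path(out_dir, "segments.csv"), row.names = FALSE)
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(coupling, file.path(out_dir, "coupling.csv"), row.names = FALSE)
  write.csv(tables$table1_lag, file.path(out_dir, "table1_lag.csv"), row.names = FALSE)
  write.csv(tables$table1_corr, file.path(out_dir, "table1_corr.csv"), row.names = FALSE)
  write.csv(tables$table2_lag, file.path(out_dir, "table2_lag.csv"), row.names = FALSE)
  write.csv(tables$table2_corr, file.path(out_dir, "table2_corr.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadsync")),
    input_hashes = in_hash,
    config = config,
    row_counts = list(segments = nrow(segments), features = nrow(features),
                      coupling = nrow(coupling)),
    output_hashes = hash_files(file.path(out_dir, out_files)),
    cached = FALSE)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(segments = segments, features = features, coupling = coupling,
                 tables = tables, manifest = manifest))
}
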