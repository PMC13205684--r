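#' Simulate one subject of the synthetic cardiac world
#'
#' Draws a cardiac state, renders its ECG, and (optionally) simulates the
#' radar measurement and runs the radar frontend to the motion tensor.
#'
#' @param rhythm rhythm class.
#' @param duration_s recording length.
#' @param seed integer seed.
#' @param subject_id identifier.
#' @param with_radar also simulate radar and build the motion tensor.
#' @param grid,rconfig radar geometry (defaults: [make_voxel_grid()],
#'   [radar_config()]).
#' @param n_clutter static clutter reflectors.
#' @param ecg_fs_hz ECG sampling rate.
#' @param state_params hyperparameter overrides for
#'   [sample_cardiac_state()].
#' @return list with `state`, `ecg` and (if requested) `motion`.
#' @export
simulate_subject <- function(rhythm, duration_s = 30, seed = 0,
                             subject_id = NULL, with_radar = TRUE,
                             grid = NULL, rconfig = NULL, n_clutter = 4,
                             ecg_fs_hz = 250, state_params = list()) {
  state <- sample_cardiac_state(rhythm, duration_s, state_params, seed = seed,
                                subject_id = subject_id)
  ecg <- render_ecg(state, fs_hz = ecg_fs_hz)
  out <- list(state = state, ecg = ecg)
  if (with_radar) {
    grid <- grid %||% make_voxel_grid()
    rconfig <- rconfig %||% radar_config()
    disp <- render_torso_displacement(state, grid,
                                      fs_hz = rconfig$chirp_rate_hz)
    clutter <- sample_clutter(grid, n_clutter, seed = seed)
    cube <- simulate_radar(disp, rconfig, clutter, seed = seed)
    out$motion <- build_motion_tensor(cube, grid)
  }
  out
}

#' Simulate a synthetic cohort
#'
#' Rhythm classes are assigned in proportion to `rhythm_mix`
#' (interleaved deterministically), each subject with its own derived seed.
#'
#' @param n_subjects cohort size.
#' @param duration_s per-subject recording length.
#' @param rhythm_mix named proportions over NORMAL/AF/PB.
#' @param seed integer seed.
#' @param ... forwarded to [simulate_subject()].
#' @return list of subjects (see [simulate_subject()]).
#' @export
simulate_cohort <- function(n_subjects, duration_s = 30,
                            rhythm_mix = c(NORMAL = 0.5, AF = 0.25, PB = 0.25),
                            seed = 0, ...) {
  counts <- round(rhythm_mix / sum(rhythm_mix) * n_subjects)
  counts[1] <- n_subjects - sum(counts[-1])
  rhythms <- withr::with_seed(derive_seed(seed, "rhythm-mix"),
                              sample(rep(names(counts), counts)))
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(rhythms[i], duration_s,
                     seed = derive_seed(seed, "subject", i),
                     subject_id = sprintf("S%03d", i), ...)
  })
}

#' Cut a cohort into synchronized paired 10-s segments
#'
#' Applies the segment protocol (10-s windows every `stride_s` seconds,
#' half-open) to every recording and collects, per segment: the ECG
#' waveform, the motion-tensor voxel matrix (when present), the beat times
#' falling inside the window (relative to its start) and the semantic
#' ground truth (mean ventricular rate, PR, QT over the window's beats; PR
#' is NA for AF, where no organized atrial conduction exists).
#'
#' @param cohort list from [simulate_cohort()].
#' @param segment_s,stride_s segment protocol (default 10 / 5).
#' @return list with `ecg` (segments x samples), `radio` (segments x
#'   voxels x frames, or NULL), `meta` (data frame: subject, recording,
#'   rhythm, start_s, hr_bpm, pr_ms, qt_ms), `beats` (list of per-segment
#'   beat times, s).
#' @export
build_paired_segments <- function(cohort, segment_s = 10, stride_s = 5) {
  first <- cohort[[1]]
  fs_e <- first$ecg$fs_hz
  n_e <- round(segment_s * fs_e)
  has_radio <- !is.null(first$motion)
  ecg_rows <- list(); radio_rows <- list(); beats <- list(); meta <- list()
  for (subj in cohort) {
    st <- subj$state
    starts <- segment_stream(st$duration_s, segment_s, stride_s)
    mm <- if (has_radio) motion_matrix(subj$motion) else NULL
    fs_r <- if (has_radio) subj$motion$fs_hz else NA
    for (t0 in starts) {
      i0 <- round(t0 * fs_e)
      seg_e <- subj$ecg$waveform[1, (i0 + 1):(i0 + n_e)]
      inw <- which(st$beat_times >= t0 & st$beat_times < t0 + segment_s)
      if (length(inw) < 2) next
      k <- length(ecg_rows) + 1
      ecg_rows[[k]] <- seg_e
      if (has_radio) {
        j0 <- round(t0 * fs_r)
        radio_rows[[k]] <- mm[, (j0 + 1):(j0 + round(segment_s * fs_r)),
                              drop = FALSE]
      }
      beats[[k]] <- st$beat_times[inw] - t0
      meta[[k]] <- data.frame(
        subject = st$subject_id, recording = st$subject_id,
        rhythm = st$rhythm, start_s = t0,
        hr_bpm = 60 / mean(diff(st$beat_times[inw])), # window ventricular rate
        pr_ms = if (st$rhythm == "AF") NA_real_ else mean(st$pr_ms[inw]),
        qt_ms = mean(st$qt_ms[inw]),
        stringsAsFactors = FALSE)
    }
  }
  n <- length(ecg_rows)
  radio <- NULL
  if (has_radio) {
    radio <- array(0, c(n, nrow(radio_rows[[1]]), ncol(radio_rows[[1]])))
    for (k in seq_len(n)) radio[k, , ] <- radio_rows[[k]]
  }
  list(ecg = do.call(rbind, ecg_rows), radio = radio,
       meta = do.call(rbind, meta), beats = beats)
}

#' Match detected to reference beats and collect IBI errors
#'
#' Greedy nearest matching within `tol_s`; IBI errors are computed between
#' consecutively matched beat pairs on both sides.
#'
#' @param detected,reference beat times, seconds.
#' @param tol_s matching tolerance (default 0.2 s).
#' @return list with `ibi_err_ms` (vector) and `n_matched`.
#' @export
match_beats <- function(detected, reference, tol_s = 0.2) {
  if (length(detected) < 2 || length(reference) < 2)
    return(list(ibi_err_ms = numeric(0), n_matched = 0))
  match_idx <- rep(NA_integer_, length(reference))
  used <- logical(length(detected))
  for (i in seq_along(reference)) {
    d <- abs(detected - reference[i])
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol_s) {
      match_idx[i] <- j
      used[j] <- TRUE
    }
  }
  errs <- numeric(0)
  for (i in seq_len(length(reference) - 1)) {
    j1 <- match_idx[i]; j2 <- match_idx[i + 1]
    if (!is.na(j1) && !is.na(j2) && j2 > j1) {
      ibi_ref <- (reference[i + 1] - reference[i]) * 1000
      ibi_det <- (detected[j2] - detected[j1]) * 1000
      errs <- c(errs, abs(ibi_det - ibi_ref))
    }
  }
  list(ibi_err_ms = errs, n_matched = sum(!is.na(match_idx)))
}
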