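#' Render a synthetic ECG record from a cardiac state
#'
#' Each beat is drawn as five parameterized Gaussian bumps (P, Q, R, S, T)
#' whose landmarks are placed analytically so that the semantic intervals of
#' the driving state are exactly recoverable from the waveform:
#' * the P-wave onset (2 SD before the P center) precedes the R peak by
#'   `pr_ms`;
#' * the Q-wave onset to T-wave end (2 SD past the T center) spans `qt_ms`.
#'
#' Atrial fibrillation is rendered with zero P-wave amplitude plus a small
#' irregular fibrillatory baseline ripple (4-9 Hz), matching its clinical
#' signature of absent consistent P waves. The record is a pure function of
#' the state (noise is seeded from `state$seed`).
#'
#' @param state a [cardiac_state][sample_cardiac_state].
#' @param fs_hz sampling rate in Hz (>= 100; default 250).
#' @param n_leads number of leads (default 1; extra leads are amplitude-scaled
#'   copies with independent sensor noise, not anatomical lead vectors).
#' @param noise_sd additive sensor noise SD in mV (default 0.01).
#' @return an object of class `ecg_record` with fields `waveform`
#'   (leads x samples matrix, mV), `fs_hz`, `lead_names`, `labels`,
#'   `state_ref`.
#' @export
render_ecg <- function(state, fs_hz = 250, n_leads = 1, noise_sd = 0.01) {
  stopifnot(inherits(state, "cardiac_state"))
  if (fs_hz < 100) stopf("fs_hz must be >= 100")
  if (n_leads < 1) stopf("n_leads must be >= 1")
  n <- round(state$duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz

  waves <- ecg_wave_params()
  base <- numeric(n)
  for (i in seq_along(state$beat_times)) {
    tr <- state$beat_times[i]
    pr <- state$pr_ms[i] / 1000
    qt <- state$qt_ms[i] / 1000
    p_amp <- if (state$rhythm == "AF") 0 else waves$p_amp
    centers <- ecg_wave_centers(tr, pr, qt, waves)
    amps <- c(P = p_amp, Q = waves$q_amp, R = waves$r_amp,
              S = waves$s_amp, T = waves$t_amp)
    sds <- c(P = waves$p_sd, Q = waves$q_sd, R = waves$r_sd,
             S = waves$s_sd, T = waves$t_sd)
    lo <- max(1L, floor((centers["P"] - 5 * sds["P"]) * fs_hz))
    hi <- min(n, ceiling((centers["T"] + 5 * sds["T"]) * fs_hz))
    if (lo > n || hi < 1) next
    idx <- lo:hi
    for (w in names(centers)) {
      base[idx] <- base[idx] +
        amps[w] * exp(-0.5 * ((t[idx] - centers[w]) / sds[w])^2)
    }
  }

  wf <- withr::with_seed(derive_seed(state$seed, "ecg-noise"), {
    out <- matrix(0, n_leads, n)
    for (l in seq_len(n_leads)) {
      lead <- base * (1 - 0.15 * (l - 1) / max(1, n_leads - 1))
      if (state$rhythm == "AF") {
        # coarse fibrillatory ripple: narrowband 4-9 Hz noise
        ripple <- stats::rnorm(n)
        ripple <- suppress_respiration(ripple, fs_hz, band = c(4, 9))
        lead <- lead + 0.04 * ripple / max(stats::sd(ripple), 1e-12)
      }
      out[l, ] <- lead + stats::rnorm(n, 0, noise_sd)
    }
    out
  })

  structure(list(
    waveform = wf, fs_hz = fs_hz,
    lead_names = paste0("L", seq_len(n_leads)),
    labels = state$rhythm, state_ref = state
  ), class = "ecg_record")
}

# Canonical wave amplitudes (mV) and widths (s) of the synthetic PQRST.
ecg_wave_params <- function() {
  list(p_amp = 0.18, p_sd = 0.022,
       q_amp = -0.12, q_sd = 0.009,
       r_amp = 1.0,  r_sd = 0.013,
       s_amp = -0.18, s_sd = 0.010,
       t_amp = 0.32, t_sd = 0.055)
}

# Wave centers (s) for one beat with R peak at `tr`, PR `pr` (s), QT `qt` (s).
ecg_wave_centers <- function(tr, pr, qt, waves = ecg_wave_params()) {
  q_center <- tr - 0.020
  q_onset <- q_center - 2 * waves$q_sd
  c(P = tr - pr + 2 * waves$p_sd,
    Q = q_center,
    R = tr,
    S = tr + 0.030,
    T = q_onset + qt - 2 * waves$t_sd)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d lead(s) x %d samples @ %g Hz (%s)\n",
              nrow(x$waveform), ncol(x$waveform), x$fs_hz,
              x$labels %||% "unlabeled"))
  invisible(x)
}

#' Write / read an ECG record as CSV
#'
#' Plain-text persistence: one column per lead plus a leading `time_s`
#' column; the sampling rate is recorded in a `# fs_hz:` header comment.
#'
#' @param record an `ecg_record`.
#' @param path file path.
#' @return `write_ecg_csv` returns `path` invisibly; `read_ecg_csv` returns
#'   an `ecg_record` (without state provenance).
#' @export
write_ecg_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz: %g", record$fs_hz), con)
  df <- data.frame(time_s = (seq_len(ncol(record$waveform)) - 1) / record$fs_hz,
                   t(record$waveform))
  names(df) <- c("time_s", record$lead_names)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  header <- readLines(path, n = 1)
  fs <- as.numeric(sub("# fs_hz:", "", header))
  if (!is.finite(fs)) stopf("missing '# fs_hz:' header in %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  wf <- t(as.matrix(df[, -1, drop = FALSE]))
  structure(list(waveform = wf, fs_hz = fs,
                 lead_names = rownames(wf), labels = NULL, state_ref = NULL),
            class = "ecg_record")
}
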