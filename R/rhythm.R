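#' Detect R peaks in an ECG waveform
#'
#' Energy-based detector in the Pan-Tompkins family: band-pass (default
#' 5-35 Hz) to isolate QRS energy, differentiate, square, moving-window
#' integration (150 ms), then an adaptive threshold at a fraction of the
#' integrated envelope's upper quantile with a 200 ms refractory period
#' (larger candidate wins). Peak times are refined to sub-sample precision
#' by parabolic interpolation on the band-passed energy. Scale-invariant
#' and deterministic.
#'
#' @param ecg numeric waveform (single lead, mV) or an `ecg_record` (first
#'   lead used).
#' @param fs_hz sampling rate (taken from the record when omitted).
#' @param band QRS energy band, Hz.
#' @param refractory_s minimum beat spacing (default 0.2 s).
#' @param threshold_frac adaptive threshold as a fraction of the 98th
#'   percentile of the integrated envelope (default 0.2).
#' @return strictly increasing beat times in seconds (possibly empty, with
#'   a warning, for flat signals).
#' @export
detect_r_peaks <- function(ecg, fs_hz = NULL, band = c(5, 35),
                           refractory_s = 0.2, threshold_frac = 0.2) {
  if (inherits(ecg, "ecg_record")) {
    fs_hz <- fs_hz %||% ecg$fs_hz
    ecg <- ecg$waveform[1, ]
  }
  if (is.null(fs_hz)) stopf("fs_hz required for a bare waveform")
  n <- length(ecg)
  if (n / fs_hz < 2) stopf("need at least 2 s of signal")
  if (stats::sd(ecg) < 1e-12) {
    warnf("flat signal: no beats detected")
    return(numeric(0))
  }
  band[2] <- min(band[2], 0.45 * fs_hz)
  bp <- suppress_respiration(ecg, fs_hz, band = band)
  energy <- c(0, diff(bp))^2
  w <- max(3L, round(0.15 * fs_hz))
  integ <- stats::filter(energy, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- threshold_frac * stats::quantile(integ, 0.98, names = FALSE)

  above <- integ > thr
  candidates <- which(above & c(FALSE, integ[-1] >= integ[-n]) &
                        c(integ[-n] > integ[-1], FALSE))
  if (length(candidates) == 0) {
    warnf("no beats detected")
    return(numeric(0))
  }
  # refractory: greedy scan, keep the larger of two close candidates
  keep <- integer(0)
  for (idx in candidates) {
    if (length(keep) > 0 && (idx - keep[length(keep)]) / fs_hz < refractory_s) {
      if (integ[idx] > integ[keep[length(keep)]]) keep[length(keep)] <- idx
    } else keep <- c(keep, idx)
  }
  # refine each beat to the local extremum of the band-passed QRS
  half <- round(0.08 * fs_hz)
  times <- vapply(keep, function(idx) {
    lo <- max(1L, idx - half)
    hi <- min(n, idx + half)
    seg <- abs(bp[lo:hi])
    pk <- lo + which.max(seg) - 1L
    # parabolic sub-sample refinement
    if (pk > 1 && pk < n) {
      y1 <- abs(bp[pk - 1]); y2 <- abs(bp[pk]); y3 <- abs(bp[pk + 1])
      den <- y1 - 2 * y2 + y3
      off <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
      (pk - 1 + max(-0.5, min(0.5, off))) / fs_hz
    } else (pk - 1) / fs_hz
  }, numeric(1))
  times <- sort(unique(times))
  # a second refractory pass on refined times
  if (length(times) > 1) {
    out <- times[1]
    for (tt in times[-1]) if (tt - out[length(out)] >= refractory_s) out <- c(out, tt)
    times <- out
  }
  times
}

#' Inter-beat intervals from beat times
#'
#' @param beat_times strictly increasing beat times, seconds (>= 2 beats).
#' @return successive differences in milliseconds (length = beats - 1).
#' @export
compute_ibi <- function(beat_times) {
  if (length(beat_times) < 2) stopf("insufficient beats: need >= 2")
  d <- diff(beat_times)
  if (any(d <= 0)) stopf("beat_times must be strictly increasing")
  d * 1000
}

#' Standard heart-rate-variability metrics from an IBI series
#'
#' * `rmssd_ms = sqrt(mean(diff(ibi)^2))` - short-term variability;
#' * `sdnn_ms` - standard deviation of the intervals (population denominator
#'   N by default; set `sd_denominator = "n-1"` for the sample version);
#' * `pnn50_pct` - percentage of successive differences strictly greater
#'   than 50 ms;
#' * `mean_hr_bpm = 60000 / mean(ibi)`.
#'
#' @param ibi_ms inter-beat intervals in milliseconds (>= 2 intervals for
#'   RMSSD/pNN50; >= 1 for SDNN).
#' @param window optional `(start_s, end_s)` annotation.
#' @param sd_denominator `"n"` (default) or `"n-1"`.
#' @return object of class `hrv_summary`.
#' @export
hrv_metrics <- function(ibi_ms, window = NULL, sd_denominator = c("n", "n-1")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(ibi_ms) == 0) stopf("empty IBI series")
  if (any(ibi_ms <= 250 | ibi_ms >= 3000))
    stopf("IBI outside physiological guard (250, 3000) ms")
  n <- length(ibi_ms)
  d <- diff(ibi_ms)
  var_pop <- mean((ibi_ms - mean(ibi_ms))^2)
  sdnn <- if (sd_denominator == "n") sqrt(var_pop) else stats::sd(ibi_ms)
  structure(list(
    ibi_ms = ibi_ms,
    mean_hr_bpm = 60000 / mean(ibi_ms),
    rmssd_ms = if (n >= 2) sqrt(mean(d^2)) else NA_real_,
    sdnn_ms = sdnn,
    pnn50_pct = if (n >= 2) 100 * sum(abs(d) > 50) / length(d) else NA_real_,
    window = window
  ), class = "hrv_summary")
}

#' @export
print.hrv_summary <- function(x, ...) {
  cat(sprintf("<hrv_summary> %d IBIs: HR %.1f bpm, RMSSD %.1f ms, SDNN %.1f ms, pNN50 %.1f%%\n",
              length(x$ibi_ms), x$mean_hr_bpm, x$rmssd_ms, x$sdnn_ms, x$pnn50_pct))
  invisible(x)
}

#' Poincare pairs of successive inter-beat intervals
#'
#' @param ibi_ms IBI series in milliseconds.
#' @return two-column matrix `(ibi_k, ibi_k1)`; `intervals - 1` rows (empty
#'   for fewer than 2 intervals).
#' @export
poincare_pairs <- function(ibi_ms) {
  n <- length(ibi_ms)
  if (n < 2) return(matrix(numeric(0), 0, 2,
                           dimnames = list(NULL, c("ibi_k", "ibi_k1"))))
  cbind(ibi_k = ibi_ms[-n], ibi_k1 = ibi_ms[-1])
}

#' Windowed HRV trend over a long recording
#'
#' Computes one [hrv_metrics()] summary per half-open window
#' `[start, start + window_s)` of beat times (default 5-minute windows, as
#' used for overnight trend monitoring). A beat exactly on a boundary
#' belongs to the later window; windows with fewer than 2 beats are skipped
#' with a message.
#'
#' @param beat_times beat times, seconds.
#' @param window_s,step_s window length and stride, seconds (default 300/300).
#' @return list of `hrv_summary` objects with `window` annotations.
#' @export
windowed_hrv <- function(beat_times, window_s = 300, step_s = 300) {
  if (length(beat_times) < 2) stopf("insufficient beats")
  starts <- seq(0, max(beat_times), by = step_s)
  out <- list()
  for (s in starts) {
    inw <- beat_times[beat_times >= s & beat_times < s + window_s]
    if (length(inw) < 2) {
      message(sprintf("window [%g, %g): fewer than 2 beats, skipped", s, s + window_s))
      next
    }
    out[[length(out) + 1]] <- hrv_metrics(compute_ibi(inw),
                                          window = c(s, s + window_s))
  }
  out
}

#' One-sided 1.5 x IQR filter for windowed predictions
#'
#' Discards values strictly above `Q3 + 1.5 * IQR` (quartiles by linear
#' interpolation, `stats::quantile` type 7). Low values are always
#' retained; the rule is one-sided by design, targeting spuriously high
#' window predictions.
#'
#' @param values numeric vector of per-window predictions (>= 4 values).
#' @return the retained values, in input order.
#' @export
filter_window_outliers <- function(values) {
  if (length(values) < 4) stopf("need >= 4 windows for the IQR rule")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  upper <- q[2] + 1.5 * (q[2] - q[1])
  values[values <= upper]
}

#' Export per-window HRV summaries as a data frame / CSV
#'
#' @param summaries list of `hrv_summary` (from [windowed_hrv()]).
#' @param path optional CSV path.
#' @return data frame with columns `window_start_s`, `mean_hr`, `sdnn`,
#'   `rmssd`, `pnn50`.
#' @export
hrv_table <- function(summaries, path = NULL) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(window_start_s = if (is.null(s$window)) NA_real_ else s$window[1],
               mean_hr = s$mean_hr_bpm, sdnn = s$sdnn_ms,
               rmssd = s$rmssd_ms, pnn50 = s$pnn50_pct)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
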