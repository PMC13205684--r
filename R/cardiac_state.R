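#' Rhythm classes supported by the synthetic cardiac world
#' @export
RHYTHM_CLASSES <- c("NORMAL", "AF", "PB")

#' Default cohort-level distribution hyperparameters for cardiac states
#'
#' Means and spreads follow typical adult outpatient physiology: resting
#' ventricular rate around 75 bpm (between-subject SD 12), PR interval
#' 160 ms (SD 22, clipped to 110-215 ms), QT interval 400 ms (SD 28,
#' clipped to 320-480 ms), breathing at 0.2-0.35 Hz. Atrial fibrillation
#' draws inter-beat intervals with a coefficient of variation of 0.24;
#' premature beats arrive roughly every 10th beat at 62% of the local
#' cycle, followed by a 1.45x compensatory pause.
#'
#' @return named list of hyperparameters.
#' @export
default_state_params <- function() {
  list(
    hr_mean = 75, hr_sd = 12,          # between-subject ventricular rate, bpm
    ibi_jitter_cv = 0.02,              # within-subject beat-to-beat jitter
    rsa_depth = 0.015,                 # respiratory sinus arrhythmia depth
    pr_mean = 160, pr_sd = 22,         # PR interval, ms
    qt_mean = 400, qt_sd = 28,         # QT interval, ms
    pr_beat_sd = 2, qt_beat_sd = 3,    # per-beat interval jitter, ms
    resp_hz_range = c(0.2, 0.35),      # breathing frequency, Hz
    af_ibi_cv = 0.24,                  # AF inter-beat irregularity (CV)
    pb_every = 10,                     # mean beats between premature beats
    pb_prematurity = 0.62,             # premature cycle / local cycle
    pb_pause = 1.45                    # compensatory pause / local cycle
  )
}

#' Sample a latent cardiac state
#'
#' Draws the shared ground-truth cardiac state that drives both the ECG
#' renderer and the radar simulator: beat times, per-beat ventricular rate,
#' PR and QT intervals, rhythm class and breathing frequency. The state is
#' a pure function of `(rhythm, duration_s, params, seed)`.
#'
#' QT is adapted per beat with a Bazett-style square-root rate correction so
#' that short (premature) cycles keep `pr + qt` inside the cycle length.
#'
#' @param rhythm one of `"NORMAL"`, `"AF"`, `"PB"`.
#' @param duration_s recording duration in seconds (>= 10).
#' @param params hyperparameters, see [default_state_params()]; partial
#'   lists are merged over the defaults.
#' @param seed integer seed.
#' @param subject_id optional identifier (default derived from the seed).
#' @return an object of class `cardiac_state`.
#' @export
sample_cardiac_state <- function(rhythm = "NORMAL", duration_s = 60,
                                 params = list(), seed = 0,
                                 subject_id = NULL) {
  rhythm <- match.arg(rhythm, RHYTHM_CLASSES)
  if (duration_s < 10) stopf("duration_s must be >= 10 (got %s)", duration_s)
  p <- utils::modifyList(default_state_params(), params)
  if (p$pr_mean + p$qt_mean >= 0.95 * 60000 / p$hr_mean) {
    stopf(paste("infeasible params: pr_mean + qt_mean (%s ms) does not fit the",
                "mean cycle length %s ms (invariant pr_ms + qt_ms < 60000/hr_bpm)"),
          p$pr_mean + p$qt_mean, round(60000 / p$hr_mean, 1))
  }
  subject_id <- subject_id %||% sprintf("synth-%s-%d", tolower(rhythm), seed)

  for (attempt in 1:25) {
    st <- withr::with_seed(derive_seed(seed, "state", attempt), {
      .draw_state(rhythm, duration_s, p, seed, subject_id)
    })
    ok <- tryCatch({ validate_cardiac_state(st); TRUE }, error = function(e) FALSE)
    if (ok) return(st)
  }
  validate_cardiac_state(st) # surface the named invariant violation
  st
}

.draw_state <- function(rhythm, duration_s, p, seed, subject_id) {
  hr_subj <- max(45, min(130, stats::rnorm(1, p$hr_mean, p$hr_sd)))
  ibi_subj <- 60 / hr_subj
  resp_hz <- stats::runif(1, p$resp_hz_range[1], p$resp_hz_range[2])
  pr_subj <- max(110, min(215, stats::rnorm(1, p$pr_mean, p$pr_sd)))
  qt_subj <- max(320, min(480, stats::rnorm(1, p$qt_mean, p$qt_sd)))

  n_max <- ceiling(duration_s / ibi_subj * 2.5) + 8
  pb_idx <- integer(0)

  if (rhythm == "AF") {
    cv <- p$af_ibi_cv
    sdlog <- sqrt(log(1 + cv^2))
    ibis <- stats::rlnorm(n_max, log(ibi_subj) - sdlog^2 / 2, sdlog)
  } else {
    t_acc <- cumsum(rep(ibi_subj, n_max))
    rsa <- p$rsa_depth * sin(2 * pi * resp_hz * t_acc)
    ibis <- ibi_subj * (1 + rsa + stats::rnorm(n_max, 0, p$ibi_jitter_cv))
    if (rhythm == "PB") {
      i <- 3L
      while (i <= n_max - 2L) {
        gap <- max(4L, stats::rpois(1, p$pb_every))
        i <- i + gap
        if (i > n_max - 2L) break
        pb_idx <- c(pb_idx, i)
        ibis[i - 1L] <- ibis[i - 1L] * p$pb_prematurity  # early arrival
        ibis[i] <- ibis[i] * p$pb_pause                  # compensatory pause
        i <- i + 1L
      }
    }
  }
  ibis <- pmin(pmax(ibis, 60 / 220), 60 / 30)
  t0 <- stats::runif(1, 0.25, 0.6)
  beat_times <- t0 + c(0, cumsum(ibis))
  keep <- beat_times <= duration_s - 0.05
  beat_times <- beat_times[keep]
  n <- length(beat_times)
  pb_idx <- pb_idx[pb_idx <= n - 1L]  # premature beat needs its following pause

  # per-beat ventricular rate from the following inter-beat interval
  ibi_next <- diff(beat_times)
  ibi_next <- c(ibi_next, ibi_next[n - 1L])
  hr_bpm <- 60 / ibi_next

  pr_ms <- pr_subj + stats::rnorm(n, 0, p$pr_beat_sd)
  qt_ms <- qt_subj * sqrt(pmin(ibi_next, 1.6) / min(ibi_subj, 1.6)) +
    stats::rnorm(n, 0, p$qt_beat_sd)
  # keep PR + QT strictly inside every cycle
  cycle_ms <- ibi_next * 1000
  over <- pr_ms + qt_ms > 0.92 * cycle_ms
  if (any(over)) {
    qt_ms[over] <- pmax(180, 0.92 * cycle_ms[over] - pr_ms[over])
  }

  structure(list(
    subject_id = subject_id, duration_s = duration_s,
    beat_times = beat_times, hr_bpm = hr_bpm,
    pr_ms = pr_ms, qt_ms = qt_ms, rhythm = rhythm,
    pb_beat_indices = pb_idx, respiration_hz = resp_hz, seed = seed
  ), class = "cardiac_state")
}

#' Validate the invariants of a cardiac state
#'
#' Checks monotone beat times, physiological rate bounds, `pr + qt` inside
#' each cycle, AF irregularity (IBI coefficient of variation >= 0.1) and the
#' compensatory pause after every premature beat (following interval at least
#' 1.1x the local mean of unaffected intervals).
#'
#' @param state a `cardiac_state`.
#' @return the state, invisibly; errors name the violated invariant.
#' @export
validate_cardiac_state <- function(state) {
  stopifnot(inherits(state, "cardiac_state"))
  bt <- state$beat_times
  if (length(bt) < 2) stopf("invariant violated: need at least 2 beats")
  if (any(diff(bt) <= 0)) stopf("invariant violated: beat_times not strictly increasing")
  if (any(state$hr_bpm < 30 | state$hr_bpm > 220))
    stopf("invariant violated: hr_bpm outside [30, 220]")
  if (any(state$pr_ms + state$qt_ms >= 60000 / state$hr_bpm))
    stopf("invariant violated: pr_ms + qt_ms >= cycle length 60000/hr_bpm")
  ibis <- diff(bt)
  if (state$rhythm == "AF") {
    cv <- stats::sd(ibis) / mean(ibis)
    if (cv < 0.1)
      stopf("invariant violated: AF requires IBI coefficient of variation >= 0.1 (got %.3f)", cv)
  }
  if (state$rhythm == "PB") {
    for (i in state$pb_beat_indices) {
      if (i >= length(bt)) stopf("invariant violated: premature beat lacks a following interval")
      affected <- unique(pmax(1, pmin(length(ibis), c(i - 1L, i))))
      nbhd <- setdiff(max(1, i - 6L):min(length(ibis), i + 6L), affected)
      if (ibis[i] < 1.1 * mean(ibis[nbhd]))
        stopf("invariant violated: compensatory pause after premature beat %d < 1.1x local mean", i)
    }
  }
  invisible(state)
}

#' @export
print.cardiac_state <- function(x, ...) {
  cat(sprintf("<cardiac_state> %s: %s, %.0f s, %d beats, mean HR %.1f bpm, PR %.0f ms, QT %.0f ms\n",
              x$subject_id, x$rhythm, x$duration_s, length(x$beat_times),
              mean(x$hr_bpm), mean(x$pr_ms), mean(x$qt_ms)))
  invisible(x)
}
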