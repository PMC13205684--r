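test_that("zero-variance sinus rhythm produces exact 1-s beat spacing", {
  st <- metronome_state(hr = 60, duration_s = 10, seed = 0)
  expect_true(length(st$beat_times) %in% c(10, 11))
  expect_equal(diff(st$beat_times), rep(1, length(st$beat_times) - 1),
               tolerance = 1e-12)
  expect_equal(st$hr_bpm, rep(60, length(st$hr_bpm)), tolerance = 1e-9)
})

test_that("cardiac states are deterministic in (rhythm, duration, params, seed)", {
  a <- sample_cardiac_state("AF", 30, seed = 7)
  b <- sample_cardiac_state("AF", 30, seed = 7)
  expect_identical(a, b)
  c <- sample_cardiac_state("AF", 30, seed = 8)
  expect_false(identical(a$beat_times, c$beat_times))
})

test_that("AF states carry irregular inter-beat intervals (CV >= 0.1)", {
  for (seed in 1:5) {
    st <- sample_cardiac_state("AF", 60, seed = seed)
    ibis <- diff(st$beat_times)
    expect_gte(sd(ibis) / mean(ibis), 0.1)
  }
})

test_that("every premature beat is followed by a compensatory pause", {
  for (seed in 1:5) {
    st <- sample_cardiac_state("PB", 60, seed = seed)
    expect_gt(length(st$pb_beat_indices), 0)
    ibis <- diff(st$beat_times)
    for (i in st$pb_beat_indices) {
      nbhd <- setdiff(max(1, i - 6):min(length(ibis), i + 6),
                      c(i - 1, i))
      expect_gte(ibis[i], 1.1 * mean(ibis[nbhd]))
      # the premature beat itself arrives early
      expect_lt(ibis[i - 1], 0.85 * mean(ibis[nbhd]))
    }
  }
})

test_that("state invariants hold across rhythms and infeasible params error", {
  for (r in RHYTHM_CLASSES) {
    st <- sample_cardiac_state(r, 30, seed = 3)
    expect_silent(validate_cardiac_state(st))
    expect_true(all(st$pr_ms + st$qt_ms < 60000 / st$hr_bpm))
    expect_true(all(st$hr_bpm >= 30 & st$hr_bpm <= 220))
  }
  expect_error(sample_cardiac_state("NORMAL", 30,
                                    params = list(pr_mean = 400, qt_mean = 500,
                                                  hr_mean = 75), seed = 0),
               "pr_mean \\+ qt_mean")
  expect_error(sample_cardiac_state("NORMAL", 5, seed = 0), "duration_s")
})

test_that("rendered R peaks sit at the state's beat times", {
  st <- metronome_state(hr = 60, duration_s = 10, seed = 1)
  rec <- render_ecg(st, fs_hz = 250, noise_sd = 0)
  wf <- rec$waveform[1, ]
  for (bt in st$beat_times) {
    idx <- round(bt * 250) + 1
    win <- wf[max(1, idx - 2):min(length(wf), idx + 2)]
    expect_gte(max(win), 0.9) # R amplitude ~1 mV at the beat time
  }
  peaks <- which(wf > 0.7)
  spacing <- diff(range(diff(peaks[c(diff(peaks) > 10, TRUE)])))
  expect_lte(spacing, 1) # 1-s spacing within one sample
})

test_that("PR landmark is recoverable from the rendered waveform within 5 ms", {
  st <- metronome_state(hr = 60, duration_s = 10, seed = 2)
  st$pr_ms[] <- 160
  fs <- 1000 # fine grid for landmark measurement
  rec <- render_ecg(st, fs_hz = fs, noise_sd = 0)
  wf <- rec$waveform[1, ]
  bt <- st$beat_times[3]
  ridx <- round(bt * fs) + 1
  # P onset = 2 SD before the P centre, where the Gaussian crosses
  # exp(-2) = 0.135 of its peak
  seg <- wf[(ridx - round(0.3 * fs)):(ridx - round(0.06 * fs))]
  p_peak <- max(seg)
  onset_rel <- which(seg > exp(-2) * p_peak)[1]
  p_onset_s <- (ridx - round(0.3 * fs) + onset_rel - 2) / fs
  measured_pr_ms <- (bt - p_onset_s) * 1000
  expect_lt(abs(measured_pr_ms - 160), 5)
})

test_that("AF rendering abolishes P waves", {
  stn <- metronome_state(hr = 70, duration_s = 20, seed = 4)
  staf <- stn
  staf$rhythm <- "AF"
  rn <- render_ecg(stn, 250, noise_sd = 0)
  raf <- render_ecg(staf, 250, noise_sd = 0)
  # consistent P amplitude: ensemble average of the P window aligned at R
  # (coherent P waves survive averaging; incoherent fibrillatory ripple
  # cancels - the clinical criterion is absence of CONSISTENT P waves)
  p_amp <- function(rec, st) {
    w <- vapply(st$beat_times[-1], function(bt) {
      i1 <- round((bt - st$pr_ms[1] / 1000) * 250)
      rec$waveform[1, i1:(i1 + round(0.022 * 4 * 250))]
    }, numeric(round(0.022 * 4 * 250) + 1))
    max(abs(rowMeans(w)))
  }
  expect_gt(p_amp(rn, stn), 0.12)     # P present in sinus rhythm
  expect_lt(p_amp(raf, staf), 0.05 * 1.0) # < 5% of R amplitude under AF
})

test_that("torso displacement responds to motion sources as modeled", {
  grid <- make_voxel_grid()
  st <- metronome_state(hr = 60, duration_s = 12, seed = 5)
  # no motion sources: constant in time everywhere
  d0 <- render_torso_displacement(st, grid, cardiac_amp_m = 0,
                                  respiration_amp_m = 0)
  expect_lt(max(apply(d0$d, 1, function(x) diff(range(x)))), 1e-15)
  # longer QT spreads the pulse and lowers its peak
  st350 <- st; st350$qt_ms[] <- 350
  st450 <- st; st450$qt_ms[] <- 450
  d350 <- render_torso_displacement(st350, grid, respiration_amp_m = 0)
  d450 <- render_torso_displacement(st450, grid, respiration_amp_m = 0)
  v <- grid$torso_idx[which.max(apply(d350$d[grid$torso_idx, ], 1, max))]
  expect_lt(max(d450$d[v, ]), max(d350$d[v, ]))
  # pulse maximum falls inside the electromechanical-delay window of a beat
  bt <- st$beat_times[3]
  tmax <- d350$t_s[which.max(d350$d[v, d350$t_s > bt - 0.3 & d350$t_s < bt + 0.4] ) +
                     sum(d350$t_s <= bt - 0.3)]
  expect_lt(abs(tmax - (bt + d350$emd_s)), 0.08)
})

test_that("radar simulation is phase-faithful and deterministic", {
  # static reflector, no noise: slow-time phase is constant
  sc <- single_scatterer_cube(rep(0, 200), noise_sigma = 0)
  ph <- Arg(sc$cube$samples[1, 1, ])
  expect_lt(diff(range(ph)), 1e-12)
  # same seed, noisy: bit-identical cubes
  st <- metronome_state(seed = 6)
  grid <- make_voxel_grid()
  disp <- render_torso_displacement(st, grid)
  cfg <- radar_config(noise_sigma = 0.05)
  c1 <- simulate_radar(disp, cfg, sample_clutter(grid, 3, 1), seed = 9)
  c2 <- simulate_radar(disp, cfg, sample_clutter(grid, 3, 1), seed = 9)
  expect_identical(c1$samples, c2$samples)
  # mismatched time base errors
  bad <- disp; bad$fs_hz <- 50
  expect_error(simulate_radar(bad, cfg, NULL, 0), "chirp rate")
})

test_that("ECG CSV round-trips waveform and sampling rate", {
  st <- metronome_state(seed = 11)
  rec <- render_ecg(st, 250, n_leads = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(rec, path)
  back <- read_ecg_csv(path)
  expect_equal(back$fs_hz, 250)
  expect_equal(dim(back$waveform), dim(rec$waveform))
  expect_equal(unname(back$waveform), unname(rec$waveform), tolerance = 1e-6)
})
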