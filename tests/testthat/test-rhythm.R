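test_that("R-peak detection matches generator beat times within 10 ms", {
  st <- metronome_state(hr = 60, duration_s = 20, seed = 20)
  rec <- render_ecg(st, 250, noise_sd = 0.01)
  det <- detect_r_peaks(rec)
  expect_equal(length(det), length(st$beat_times))
  expect_lt(max(abs(det - st$beat_times)) * 1000, 10)
  # amplitude scaling leaves peak times unchanged (adaptive threshold)
  det10 <- detect_r_peaks(rec$waveform[1, ] * 10, 250)
  expect_equal(det10, det, tolerance = 1e-12)
})

test_that("detector enforces the refractory period and flags flat input", {
  fs <- 250
  t <- (0:(fs * 6 - 1)) / fs
  # two fused spikes 150 ms apart once per second: one beat kept
  x <- numeric(length(t))
  for (b in 1:5) {
    x <- x + exp(-0.5 * ((t - b) / 0.012)^2) +
      0.9 * exp(-0.5 * ((t - b - 0.15) / 0.012)^2)
  }
  det <- detect_r_peaks(x, fs)
  expect_equal(length(det), 5)
  expect_true(all(diff(det) >= 0.2))
  expect_warning(out <- detect_r_peaks(rep(0.3, fs * 3), fs), "flat")
  expect_length(out, 0)
})

test_that("inter-beat intervals follow the defining arithmetic", {
  expect_equal(compute_ibi(c(1, 2, 3)), c(1000, 1000))
  expect_error(compute_ibi(1.5), "insufficient")
  expect_error(compute_ibi(c(2, 1.5)), "strictly increasing")
})

test_that("HRV metrics reproduce hand-computed cases", {
  # constant 800 ms: zero variability, HR 75
  h <- hrv_metrics(rep(800, 100))
  expect_equal(h$rmssd_ms, 0)
  expect_equal(h$sdnn_ms, 0)
  expect_equal(h$pnn50_pct, 0)
  expect_equal(h$mean_hr_bpm, 75)
  # alternating 800/900: diffs (100, -100, 100)
  h2 <- hrv_metrics(c(800, 900, 800, 900))
  expect_equal(h2$rmssd_ms, 100)
  expect_equal(h2$sdnn_ms, 50)
  expect_equal(h2$pnn50_pct, 100)
  # successive differences of exactly 50 ms do NOT count (strict >)
  h3 <- hrv_metrics(seq(500, 950, by = 50))
  expect_equal(h3$pnn50_pct, 0)
  expect_error(hrv_metrics(numeric(0)), "empty")
  expect_error(hrv_metrics(c(800, 100)), "physiological")
})

test_that("HRV metrics agree with a straight-from-formula oracle to 1e-12", {
  withr::with_seed(31, {
    for (rep in 1:1000) {
      n <- sample(2:40, 1)
      ibi <- runif(n, 300, 1500)
      h <- hrv_metrics(ibi)
      d <- diff(ibi)
      expect_equal(h$rmssd_ms, sqrt(sum(d^2) / length(d)), tolerance = 1e-12)
      expect_equal(h$sdnn_ms, sqrt(sum((ibi - sum(ibi) / n)^2) / n),
                   tolerance = 1e-12)
      expect_equal(h$pnn50_pct, 100 * sum(abs(d) > 50) / length(d),
                   tolerance = 1e-12)
      expect_equal(h$mean_hr_bpm, 60000 / (sum(ibi) / n), tolerance = 1e-12)
    }
  })
})

test_that("Poincare pairs enumerate successive-interval coordinates", {
  p <- poincare_pairs(c(800, 900, 800, 900))
  expect_equal(unname(p[, 1]), c(800, 900, 800))
  expect_equal(unname(p[, 2]), c(900, 800, 900))
  # constant series collapses onto the identity line
  pc <- poincare_pairs(rep(700, 5))
  expect_true(all(pc[, 1] == pc[, 2]))
  expect_equal(nrow(poincare_pairs(800)), 0)
})

test_that("windowed HRV partitions beats into half-open windows", {
  beats <- seq(0.5, 599.5, by = 1) # 10 min at 60 bpm
  w <- windowed_hrv(beats, 300, 300)
  expect_length(w, 2)
  expect_equal(w[[1]]$mean_hr_bpm, w[[2]]$mean_hr_bpm)
  expect_equal(w[[1]]$window, c(0, 300))
  # a beat exactly on the boundary belongs to the later window
  beats2 <- c(seq(0, 299, 1), 300, seq(301, 599, 1))
  w2 <- windowed_hrv(beats2, 300, 300)
  expect_length(w2, 2)
  expect_equal(vapply(w2, function(s) length(s$ibi_ms) + 1L, integer(1)),
               c(300L, 300L)) # every beat in exactly one window
  expect_message(windowed_hrv(c(1, 2, 3, 601), 300, 300), "skipped")
  tab <- hrv_table(w)
  expect_named(tab, c("window_start_s", "mean_hr", "sdnn", "rmssd", "pnn50"))
})

test_that("the one-sided 1.5 IQR rule removes exactly the high outliers", {
  expect_equal(filter_window_outliers(c(1, 1, 1, 1, 100)), c(1, 1, 1, 1))
  expect_equal(filter_window_outliers(rep(3, 6)), rep(3, 6))
  expect_equal(filter_window_outliers(c(1, 2, 3, 4)), c(1, 2, 3, 4))
  # low values are retained: the rule is one-sided
  expect_equal(filter_window_outliers(c(-50, 1, 1, 1, 1)), c(-50, 1, 1, 1, 1))
  expect_error(filter_window_outliers(c(1, 2, 3)), ">= 4")
})
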