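test_that("K-fold partition is subject-disjoint, balanced and deterministic", {
  subj <- sprintf("S%02d", 1:14)
  f <- kfold_split(subj, k = 7, seed = 1)
  expect_equal(as.vector(table(f)), rep(2L, 7))
  expect_setequal(names(f), subj)
  expect_identical(f, kfold_split(subj, k = 7, seed = 1))
  # unbalanced counts differ by at most one
  f2 <- kfold_split(sprintf("S%02d", 1:16), k = 7, seed = 2)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(kfold_split(subj[1:5], k = 7), "at least k")
})

test_that("segment starts follow the half-open sliding-window protocol", {
  expect_equal(segment_stream(30), c(0, 5, 10, 15, 20))
  expect_equal(segment_stream(10), 0)
  expect_equal(segment_stream(9), numeric(0))
  expect_equal(segment_stream(60, segment_s = 10, stride_s = 10),
               seq(0, 50, 10))
})

test_that("bootstrap CI degenerates correctly and is seeded", {
  expect_equal(unname(bootstrap_ci(rep(4.2, 30), B = 100)), c(4.2, 4.2))
  withr::with_seed(50, x <- rnorm(200))
  ci1 <- bootstrap_ci(x, B = 500, seed = 3)
  expect_identical(ci1, bootstrap_ci(x, B = 500, seed = 3))
  expect_lt(ci1["lower"], ci1["upper"])
  expect_error(bootstrap_ci(x, B = 0), "B must be")
})

test_that("bootstrap CI of the mean achieves near-nominal coverage", {
  hits <- 0
  for (rep in 1:100) {
    x <- withr::with_seed(1000 + rep, rnorm(1000))
    ci <- bootstrap_ci(x, B = 400, statistic = mean, seed = rep)
    if (ci["lower"] <= 0 && 0 <= ci["upper"]) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("correlation report matches its closed-form endpoints", {
  x <- c(0.4, 1.3, -0.2, 2.2, 0.9)
  expect_equal(correlation_report(x, x)$r, 1)
  expect_equal(correlation_report(x, -x)$r, -1)
  expect_error(correlation_report(x[1:2], x[1:2]), "n >= 3")
  # independent normals: |R| stays small at n = 1000
  small <- 0
  for (rep in 1:100) {
    xy <- withr::with_seed(2000 + rep, matrix(rnorm(2000), ncol = 2))
    if (abs(correlation_report(xy[, 1], xy[, 2])$r) < 0.1) small <- small + 1
  }
  expect_gte(small, 95)
})

test_that("F1 scores follow the one-vs-rest definition", {
  truth <- c("AF", "AF", "NORMAL", "PB", "NORMAL")
  called <- c("AF", "NORMAL", "NORMAL", "PB", "AF")
  # AF: TP 1, FP 1, FN 1 -> 2/(2+1+1)
  expect_equal(f1_score(called, truth, "AF"), 0.5)
  expect_equal(f1_score(called, truth, "PB"), 1)
  expect_true(is.na(f1_score(called, truth, "SVT")))
})

test_that("paired segmentation aligns truth, beats and both modalities", {
  cohort <- list(simulate_subject("NORMAL", 20, seed = 77, with_radar = FALSE),
                 simulate_subject("AF", 20, seed = 78, with_radar = FALSE))
  seg <- build_paired_segments(cohort)
  expect_equal(nrow(seg$ecg), nrow(seg$meta))
  expect_equal(length(seg$beats), nrow(seg$meta))
  expect_true(all(seg$meta$start_s %in% c(0, 5, 10)))
  # PR truth is undefined (NA) for AF segments, defined otherwise
  expect_true(all(is.na(seg$meta$pr_ms[seg$meta$rhythm == "AF"])))
  expect_true(all(is.finite(seg$meta$pr_ms[seg$meta$rhythm == "NORMAL"])))
  # HR truth is the window ventricular rate of the in-window beats
  st <- cohort[[1]]$state
  i <- which(seg$meta$subject == st$subject_id & seg$meta$start_s == 5)
  inw <- st$beat_times >= 5 & st$beat_times < 15
  expect_equal(seg$meta$hr_bpm[i], 60 / mean(diff(st$beat_times[inw])))
  expect_equal(seg$beats[[i]], st$beat_times[inw] - 5)
})

test_that("beat matching tolerates misses and reports IBI errors", {
  ref <- c(1, 2, 3, 4, 5)
  det <- c(1.01, 2.02, 3.99, 5.01) # beat 3 missed
  mb <- match_beats(det, ref)
  expect_equal(mb$n_matched, 4)
  # consecutive matched pairs: (1,2) and (4,5)
  expect_equal(length(mb$ibi_err_ms), 2)
  expect_lt(max(mb$ibi_err_ms), 35)
  none <- match_beats(c(10, 11), ref)
  expect_equal(none$n_matched, 0)
})

test_that("YAML experiment configuration round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "n_paired_subjects: 12", "duration_s: 20",
               "ecg_vae:", "  epochs: 2", "radio:", "  epochs: 2"), path)
  cfg <- read_experiment_yaml(path)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$seed, 5)
  expect_equal(cfg$n_paired_subjects, 12)
  expect_equal(cfg$ecg_vae$epochs, 2)
})
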