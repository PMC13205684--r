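test_that("beamforming with zero path length is the identity", {
  # single pair at the voxel position: d_m(p) = 0, weight exp(0) = 1
  g <- make_voxel_grid(1, 1, 1, extent_xy = 0, z_range = c(0, 0))
  sc <- single_scatterer_cube(1e-4 * sin(2 * pi * (0:99) / 50), grid = g,
                              pair_positions = matrix(0, 1, 3))
  bf <- beamform(sc$cube, g)
  expect_equal(bf$series[1, ], sc$cube$samples[1, 1, ], tolerance = 1e-12)
})

test_that("beamformer power argmax localizes a point scatterer on the grid", {
  grid <- make_voxel_grid(8, 8, 4)
  target <- 29L # an interior torso-layer node
  sc <- single_scatterer_cube(2e-4 * sin(2 * pi * 1.1 * (0:199) / 100),
                              n_pairs = 4, n_fast = 16, grid = grid,
                              voxel = target)
  bf <- beamform(sc$cube, grid)
  expect_equal(which.max(bf$power), target)
})

test_that("vectorized beamformer matches the naive triple-loop oracle", {
  st <- metronome_state(seed = 12, duration_s = 10)
  grid <- make_voxel_grid()
  disp <- render_torso_displacement(st, grid)
  cube <- simulate_radar(disp, radar_config(), sample_clutter(grid, 4, 2),
                         seed = 3)
  cube$samples <- cube$samples[, , 1:40, drop = FALSE] # short slow-time window
  fast <- beamform(cube)$series
  slow <- beamform_reference(cube)
  expect_lt(max(Mod(fast - slow)) / max(Mod(slow)), 1e-9)
})

test_that("beamforming is linear in the received cube", {
  sc1 <- single_scatterer_cube(1e-4 * sin(2 * pi * (0:99) / 40), n_pairs = 2,
                               n_fast = 4)
  sc2 <- single_scatterer_cube(2e-4 * cos(2 * pi * (0:99) / 30), n_pairs = 2,
                               n_fast = 4)
  mix <- sc1$cube
  mix$samples <- 2 * sc1$cube$samples - 3i * sc2$cube$samples
  lhs <- beamform(mix)$series
  rhs <- 2 * beamform(sc1$cube)$series - 3i * beamform(sc2$cube)$series
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("extract_phase recovers the closed-form modulation amplitude", {
  # 0.25 mm one-way (0.5 mm round-trip) sinusoid at lambda = 5 mm:
  # phase amplitude 2*pi*0.5/5 = 0.628 rad
  t <- (0:999) / 100
  sc <- single_scatterer_cube(0.25e-3 * sin(2 * pi * 1.2 * t))
  ph <- extract_phase(beamform(sc$cube)$series[1, ])
  amp <- (max(ph) - min(ph)) / 2
  expect_lt(abs(amp - 2 * pi * 0.5 / 5) / (2 * pi * 0.5 / 5), 0.02)
})

test_that("extract_phase unwraps across the +/- pi branch and centres", {
  # large displacement forces multiple branch crossings
  t <- (0:499) / 100
  sc <- single_scatterer_cube(4e-3 * sin(2 * pi * 0.9 * t))
  ph <- extract_phase(beamform(sc$cube)$series[1, ])
  expect_lt(max(abs(diff(ph))), pi)
  expect_equal(mean(ph), 0, tolerance = 1e-9)
  # constant series: zero-variance phase
  cc <- rep(1 + 1i, 100)
  expect_equal(var(extract_phase(cc)), 0)
  expect_error(extract_phase(rep(0i, 50)), "all-zero")
})

test_that("torso localization ranks cardiac motion above static clutter", {
  grid <- make_voxel_grid(4, 4, 2)
  grid$torso_idx <- 6L # lone moving scatterer among implicit statics
  st <- metronome_state(hr = 72, duration_s = 20, seed = 13)
  disp <- render_torso_displacement(st, grid, respiration_amp_m = 0)
  cube <- simulate_radar(disp, radar_config(), sample_clutter(grid, 5, 4),
                         seed = 5)
  vox <- beamform(cube)
  expect_true(6L %in% localize_torso(vox, top_k = 3))
  # top_k = grid size selects everything
  expect_setequal(localize_torso(vox, top_k = 32), 1:32)
  expect_error(localize_torso(vox, top_k = 33), "top_k")
})

test_that("localization tie-breaks toward the lower flat index", {
  g <- make_voxel_grid(2, 1, 1, extent_xy = 0.05, z_range = c(0.5, 0.5))
  series <- matrix(rep(exp(1i * 0.3 * sin(2 * pi * 1.5 * (0:199) / 100)),
                       each = 2), nrow = 2)
  vox <- structure(list(series = series, power = rowMeans(Mod(series)^2),
                        grid = g, fs_hz = 100), class = "voxel_signals")
  expect_identical(localize_torso(vox, top_k = 1), 1L)
})

test_that("respiration suppression passes cardiac and rejects breathing", {
  fs <- 100
  t <- (0:2999) / fs
  resp <- sin(2 * pi * 0.25 * t)
  card <- sin(2 * pi * 1.2 * t)
  expect_lt(sd(suppress_respiration(resp, fs)) / sd(resp), 0.10)
  expect_gt(sd(suppress_respiration(card, fs)) / sd(card), 0.90)
  expect_identical(suppress_respiration(numeric(100) , fs), numeric(100))
  expect_error(suppress_respiration(card, fs, band = c(30, 60)), "band")
  expect_error(suppress_respiration(card[1:10], fs), "too short")
})

test_that("motion tensor isolates one pulse per beat and is deterministic", {
  grid <- make_voxel_grid()
  st <- metronome_state(hr = 60, duration_s = 12, seed = 14)
  disp <- render_torso_displacement(st, grid)
  cfg <- radar_config(noise_sigma = 0)
  cube <- simulate_radar(disp, cfg, NULL, seed = 0)
  mt1 <- build_motion_tensor(cube)
  mt2 <- build_motion_tensor(cube)
  expect_identical(mt1$values, mt2$values)
  mm <- motion_matrix(mt1)
  v <- which.max(apply(mm, 1, sd))
  # count dominant pulses: local maxima above half the global max
  x <- mm[v, ]
  pk <- which(x > 0.5 * max(x) & c(FALSE, diff(x) > 0) & c(diff(x) < 0, FALSE))
  expect_equal(length(pk), length(st$beat_times), tolerance = 1)
  # static-only scene: tensor stays at the noise floor
  d0 <- render_torso_displacement(st, grid, cardiac_amp_m = 0,
                                  respiration_amp_m = 0)
  cube0 <- simulate_radar(d0, cfg, NULL, seed = 0)
  vox0 <- beamform(cube0)
  expect_error(localize_torso(vox0, 4), NA) # runs; flat phases rank arbitrarily
  mt0 <- suppressWarnings(build_motion_tensor(cube0))
  expect_lt(max(abs(mt0$values)), 1e-6)
})

test_that("recovered voxel series tracks the true displacement (r >= 0.98)", {
  t <- (0:1999) / 100
  d_true <- 3e-4 * sin(2 * pi * 1.3 * t) + 1.5e-4 * sin(2 * pi * 2.1 * t)
  sc <- single_scatterer_cube(d_true, n_pairs = 2, n_fast = 8)
  mt <- build_motion_tensor(sc$cube, sc$grid, top_k = 1)
  rec <- motion_matrix(mt)[1, ]
  expect_gt(abs(cor(rec, d_true)), 0.98)
})
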