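# Shared fixtures and oracles, built in code at test time.

# central-difference numerical gradient of a scalar function
num_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# metronome state: zero-variance sinus rhythm at a given rate
metronome_state <- function(hr = 60, duration_s = 10, seed = 0) {
  sample_cardiac_state("NORMAL", duration_s,
                       params = list(hr_mean = hr, hr_sd = 0,
                                     ibi_jitter_cv = 0, rsa_depth = 0),
                       seed = seed)
}

# single-scatterer scene: one voxel grid point carrying a prescribed
# one-way displacement series; returns the simulated cube and the grid
single_scatterer_cube <- function(disp_one_way, fs_hz = 100,
                                  lambda_m = 0.005, n_pairs = 1, n_fast = 1,
                                  noise_sigma = 0, grid = NULL, voxel = 1L,
                                  seed = 0, pair_positions = NULL) {
  grid <- grid %||% {
    g <- make_voxel_grid(1, 1, 1, extent_xy = 0, z_range = c(0.5, 0.5))
    g
  }
  grid$torso_idx <- as.integer(voxel) # the single reflector in the scene
  st <- metronome_state(seed = seed)
  d <- matrix(0, nrow(grid$coords), length(disp_one_way))
  d[voxel, ] <- disp_one_way
  disp <- structure(list(d = d, t_s = (seq_along(disp_one_way) - 1) / fs_hz,
                         fs_hz = fs_hz, grid = grid, state_ref = st,
                         emd_s = 0.05),
                    class = "displacement_field")
  cfg <- radar_config(carrier_hz = 299792458 / lambda_m,
                      bandwidth_hz = if (n_fast > 1) 4e9 else 0,
                      n_pairs = n_pairs, n_fast = n_fast,
                      chirp_rate_hz = fs_hz, noise_sigma = noise_sigma,
                      pair_positions = pair_positions)
  list(cube = simulate_radar(disp, cfg, NULL, seed = seed), grid = grid,
       config = cfg, disp = disp)
}

# tiny ECG-VAE config for fast unit tests (25 Hz, shallow)
tiny_vae_config <- function(...) {
  base <- list(latent_dim = 6, depth = 2, conv_channels = c(4, 6),
               fs_hz = 25, segment_s = 10, epochs = 4, batch_size = 8)
  do.call(ecg_vae_config, utils::modifyList(base, list(...)))
}

# tiny radio config matched to a 12-voxel, 20 Hz motion input
tiny_radio_config <- function(...) {
  base <- list(latent_dim = 6, n_voxels = 12, spatial_channels = 3,
               conv_channels = c(4, 6), fs_hz = 20, segment_s = 10,
               pool = 1, epochs = 4, batch_size = 8)
  do.call(radio_model_config, utils::modifyList(base, list(...)))
}

# deterministic pseudo-ECG segments for tiny-VAE tests: PQRST-free bumps
tiny_segments <- function(n, config, seed = 0) {
  withr::with_seed(seed, {
    t <- seq(0, config$segment_s, length.out = config$n_raw)
    do.call(rbind, lapply(seq_len(n), function(i) {
      f <- runif(1, 0.8, 2)
      0.8 * sin(2 * pi * f * t) + 0.1 * rnorm(config$n_raw)
    }))
  })
}
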