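#' FMCW radar configuration
#'
#' Desk-scale defaults model a 60 GHz FMCW radar with 4 GHz sweep bandwidth
#' (5 mm carrier wavelength), M = 4 colocated transmitter-receiver antenna
#' pairs on a small 2D aperture, N = 16 fast-time samples per chirp and a
#' 100 Hz slow-time frame rate. Fast-time sample n carries the wavelength of
#' the frequency `carrier + bandwidth * (n-1)/(N-1)`.
#'
#' @param carrier_hz carrier frequency (default 60e9).
#' @param bandwidth_hz sweep bandwidth (default 4e9).
#' @param n_pairs number of antenna pairs M (default 4).
#' @param n_fast fast-time samples per chirp N (default 16).
#' @param chirp_rate_hz slow-time frame rate (default 100).
#' @param noise_sigma complex additive noise scale (default 0.02).
#' @param pair_positions optional M x 3 matrix of pair positions (metres);
#'   default: a square aperture of side 4 wavelengths around the origin.
#' @return object of class `radar_config` with derived `wavelength_m` and
#'   per-sample wavelengths `lambda_n`.
#' @export
radar_config <- function(carrier_hz = 60e9, bandwidth_hz = 4e9,
                         n_pairs = 4, n_fast = 16, chirp_rate_hz = 100,
                         noise_sigma = 0.02, pair_positions = NULL) {
  if (n_pairs < 1 || n_fast < 1) stopf("need n_pairs >= 1 and n_fast >= 1")
  wavelength_m <- SPEED_OF_LIGHT / carrier_hz
  if (is.null(pair_positions)) {
    a <- 2 * wavelength_m
    pair_positions <- cbind(
      x = rep_len(c(-a, a), n_pairs),
      y = rep(c(-a, a), each = 2, length.out = n_pairs),
      z = 0
    )[seq_len(n_pairs), , drop = FALSE]
  }
  stopifnot(nrow(pair_positions) == n_pairs, ncol(pair_positions) == 3)
  f_n <- if (n_fast == 1) carrier_hz else
    carrier_hz + bandwidth_hz * (seq_len(n_fast) - 1) / (n_fast - 1)
  structure(list(
    carrier_hz = carrier_hz, bandwidth_hz = bandwidth_hz,
    wavelength_m = wavelength_m, lambda_n = SPEED_OF_LIGHT / f_n,
    n_pairs = n_pairs, n_fast = n_fast, chirp_rate_hz = chirp_rate_hz,
    noise_sigma = noise_sigma, pair_positions = pair_positions
  ), class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf("<radar_config> %.0f GHz / %.1f GHz BW, lambda %.2f mm, M=%d, N=%d, %g Hz chirps\n",
              x$carrier_hz / 1e9, x$bandwidth_hz / 1e9, x$wavelength_m * 1e3,
              x$n_pairs, x$n_fast, x$chirp_rate_hz))
  invisible(x)
}

#' Sample static clutter reflectors
#'
#' K static point reflectors with log-uniform amplitudes in `[0.1, 3]`,
#' placed uniformly inside the grid volume away from the torso surface.
#'
#' @param grid voxel grid from [make_voxel_grid()].
#' @param k number of reflectors.
#' @param seed integer seed.
#' @return list with `positions` (k x 3) and `amplitude` (length k).
#' @export
sample_clutter <- function(grid, k = 5, seed = 0) {
  if (k == 0) return(list(positions = matrix(0, 0, 3), amplitude = numeric(0)))
  withr::with_seed(derive_seed(seed, "clutter"), {
    rng <- apply(grid$coords, 2, range)
    pos <- cbind(stats::runif(k, rng[1, 1], rng[2, 1]),
                 stats::runif(k, rng[1, 2], rng[2, 2]),
                 stats::runif(k, rng[1, 3] + 0.08, rng[2, 3]))
    list(positions = pos, amplitude = exp(stats::runif(k, log(0.1), log(3))))
  })
}

#' Simulate the raw FMCW radar cube from a displacement field
#'
#' For every antenna pair m, fast-time sample n and slow-time frame t the
#' received sample is the coherent sum over reflectors r of
#' `a_r * exp(+j * 2*pi * d_m(r, t) / lambda_n)` plus complex Gaussian noise,
#' where `d_m(r, t)` is the round-trip path through the (displaced) reflector:
#' `2 * |p_r - p_m| + 2 * disp_r(t)` (radial displacement convention, so the
#' phase convention `phi = 2*pi*d/lambda` holds with d the round-trip path).
#' Reflectors are the torso-surface voxels of the displacement field (with
#' the cardiac spatial taper as reflectivity) plus optional static clutter.
#'
#' @param displacement a `displacement_field` from
#'   [render_torso_displacement()], sampled at `config$chirp_rate_hz`.
#' @param config a [radar_config()].
#' @param clutter list from [sample_clutter()] (or NULL for none).
#' @param seed integer seed for the measurement noise.
#' @return object of class `radar_cube`: `samples` (complex array
#'   M x N x T), `config`, `t_slow_s`.
#' @export
simulate_radar <- function(displacement, config, clutter = NULL, seed = 0) {
  stopifnot(inherits(displacement, "displacement_field"),
            inherits(config, "radar_config"))
  if (abs(displacement$fs_hz - config$chirp_rate_hz) > 1e-9)
    stopf("displacement sampled at %g Hz but chirp rate is %g Hz",
          displacement$fs_hz, config$chirp_rate_hz)
  grid <- displacement$grid
  tor <- grid$torso_idx
  refl_pos <- grid$coords[tor, , drop = FALSE]
  # reflectivity follows the cardiac spatial taper plus a floor, so strong
  # movers are also strong reflectors (torso surface facing the radar)
  refl_amp <- rep(1, length(tor))
  refl_disp <- displacement$d[tor, , drop = FALSE]
  if (!is.null(clutter) && length(clutter$amplitude) > 0) {
    refl_pos <- rbind(refl_pos, clutter$positions)
    refl_amp <- c(refl_amp, clutter$amplitude)
    refl_disp <- rbind(refl_disp,
                       matrix(0, length(clutter$amplitude), ncol(refl_disp)))
  }
  n_t <- ncol(refl_disp)
  m <- config$n_pairs
  n_f <- config$n_fast
  r <- nrow(refl_pos)

  # static round-trip baselines per (pair, reflector)
  base <- matrix(0, m, r)
  for (mm in seq_len(m)) {
    dif <- refl_pos - matrix(config$pair_positions[mm, ], r, 3, byrow = TRUE)
    base[mm, ] <- 2 * sqrt(rowSums(dif^2))
  }

  samples <- array(0i, dim = c(m, n_f, n_t))
  for (nn in seq_len(n_f)) {
    lam <- config$lambda_n[nn]
    # moving part exp(j * 2*pi * (2*disp) / lambda_n): reflector x time
    mov <- exp((2i * pi / lam) * (2 * refl_disp))
    stat <- exp((2i * pi / lam) * base) * matrix(refl_amp, m, r, byrow = TRUE)
    samples[, nn, ] <- stat %*% mov
  }
  if (config$noise_sigma > 0) {
    noise <- withr::with_seed(derive_seed(seed, "radar-noise"), {
      complex(real = stats::rnorm(m * n_f * n_t, 0, config$noise_sigma),
              imaginary = stats::rnorm(m * n_f * n_t, 0, config$noise_sigma))
    })
    samples <- samples + array(noise, dim = dim(samples))
  }
  structure(list(samples = samples, config = config,
                 t_slow_s = displacement$t_s,
                 grid = grid, subject_id = displacement$state_ref$subject_id),
            class = "radar_cube")
}

#' @export
print.radar_cube <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<radar_cube> M=%d pairs x N=%d fast x T=%d slow (%.1f s @ %g Hz)\n",
              d[1], d[2], d[3], d[3] / x$config$chirp_rate_hz,
              x$config$chirp_rate_hz))
  invisible(x)
}
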