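#' Build the default desk-scale voxel grid and torso geometry
#'
#' Right-handed Cartesian frame with the radar at the origin looking down +z.
#' The grid spans a torso-sized window centred on the line of sight; the
#' torso surface is modelled as the central patch of the nearest z-layer,
#' about 0.45 m from the radar.
#'
#' @param nx,ny,nz grid dimensions (defaults 8 x 8 x 4).
#' @param extent_xy half-width of the x/y window in metres.
#' @param z_range z range of the grid in metres.
#' @return list with `coords` (V x 3 matrix, flat index = x fastest), `dims`,
#'   `torso_idx` (flat indices of torso-surface voxels) and `heart_center`
#'   (3-vector, where cardiac motion is strongest).
#' @export
make_voxel_grid <- function(nx = 8, ny = 8, nz = 4,
                            extent_xy = 0.21, z_range = c(0.45, 0.75)) {
  xs <- seq(-extent_xy, extent_xy, length.out = nx)
  ys <- seq(-extent_xy, extent_xy, length.out = ny)
  zs <- seq(z_range[1], z_range[2], length.out = nz)
  coords <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dims <- c(nx, ny, nz)
  # torso surface: all (x, y) of the first z-layer
  torso_idx <- which(coords[, 3] == zs[1])
  heart_center <- c(-extent_xy / 3, extent_xy / 5, zs[1])
  list(coords = coords, dims = dims, torso_idx = torso_idx,
       heart_center = heart_center)
}

#' Render the torso-surface displacement field driven by a cardiac state
#'
#' Cardiac mechanical activity reaches the torso surface as one sub-millimetre
#' pulse per beat, delayed from the R peak by a fixed electromechanical lag.
#' Each pulse is an energy-normalised Gaussian whose width scales with the
#' beat's QT interval, so a longer QT spreads the pulse over the longer
#' contraction-relaxation cycle and lowers its peak. The atrial kick appears
#' as a smaller precursor bump one PR interval before the ventricular pulse,
#' so atrioventricular timing is mechanically observable. Respiration adds a
#' broad sinusoid; off-torso voxels carry only a static offset.
#'
#' @param state a [cardiac_state][sample_cardiac_state].
#' @param grid voxel grid from [make_voxel_grid()].
#' @param fs_hz slow-time sampling rate (default 100 Hz).
#' @param cardiac_amp_m peak ventricular surface displacement (one-way,
#'   metres; default 5e-4).
#' @param respiration_amp_m respiration displacement amplitude (default 2e-3).
#' @param emd_s electromechanical delay between R peak and pulse peak
#'   (default 0.05 s).
#' @return list of class `displacement_field`: `d` (V x T matrix, metres,
#'   one-way radial displacement), `t_s`, `fs_hz`, `grid`, `state_ref`.
#' @export
render_torso_displacement <- function(state, grid, fs_hz = 100,
                                      cardiac_amp_m = 5e-4,
                                      respiration_amp_m = 2e-3,
                                      emd_s = 0.05) {
  stopifnot(inherits(state, "cardiac_state"))
  if (length(grid$torso_idx) == 0) stopf("grid has no torso voxels")
  if (cardiac_amp_m < 0 || respiration_amp_m < 0) stopf("amplitudes must be >= 0")
  n_t <- round(state$duration_s * fs_hz)
  t <- (seq_len(n_t) - 1) / fs_hz
  v <- nrow(grid$coords)

  pulse <- cardiac_pulse_train(state, t, emd_s)
  resp <- sin(2 * pi * state$respiration_hz * t +
                2 * pi * (state$seed %% 97) / 97)

  d <- matrix(0, v, n_t)
  static <- withr::with_seed(derive_seed(state$seed, "static-offset"),
                             stats::runif(v, -1e-4, 1e-4))
  d <- d + static # static offset everywhere (constant in t)

  # spatial weights on the torso patch: cardiac motion peaks near the heart;
  # respiration moves the chest wall almost as a unit (a near-uniform field -
  # large differential breathing phase across one beam cell would scramble
  # the coherent sum of reflectors, which real chests do not do)
  tor <- grid$torso_idx
  dist_heart <- sqrt(rowSums((grid$coords[tor, 1:2, drop = FALSE] -
                                matrix(grid$heart_center[1:2], length(tor), 2,
                                       byrow = TRUE))^2))
  w_card <- exp(-0.5 * (dist_heart / 0.09)^2)
  w_resp <- 0.92 + 0.08 * exp(-0.5 * (dist_heart / 0.3)^2)

  d[tor, ] <- d[tor, ] +
    outer(w_card, cardiac_amp_m * pulse) +
    outer(w_resp, respiration_amp_m * resp)

  structure(list(d = d, t_s = t, fs_hz = fs_hz, grid = grid,
                 state_ref = state, emd_s = emd_s),
            class = "displacement_field")
}

#' Cardiac mechanical pulse train (unit peak at reference QT)
#'
#' One ventricular pulse per beat at `beat_time + emd_s` with width
#' `sigma = 0.18 * qt_s` and energy-normalised amplitude
#' `sqrt(sigma_ref / sigma)` (reference QT 400 ms), plus an atrial precursor
#' at 30% amplitude one PR interval earlier.
#'
#' @keywords internal
cardiac_pulse_train <- function(state, t, emd_s = 0.05) {
  out <- numeric(length(t))
  sigma_ref <- 0.18 * 0.400
  atrial <- state$rhythm != "AF" # fibrillating atria produce no organized kick
  for (i in seq_along(state$beat_times)) {
    tc <- state$beat_times[i] + emd_s
    sigma <- 0.18 * state$qt_ms[i] / 1000
    amp <- sqrt(sigma_ref / sigma)
    out <- out + amp * exp(-0.5 * ((t - tc) / sigma)^2)
    if (atrial) {
      ta <- tc - state$pr_ms[i] / 1000
      out <- out + 0.3 * amp * exp(-0.5 * ((t - ta) / (0.6 * sigma))^2)
    }
  }
  out
}
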