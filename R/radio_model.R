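#' Configuration of the radio semantic representation model
#'
#' The radio encoder compresses the spatiotemporal motion tensor with a
#' learned spatial projection (1x1 convolution over voxel channels) followed
#' by a strided temporal-convolution stack, ending in a deterministic
#' 64-dimensional latent (the objective carries no KL term, so the encoder
#' is not variational). The decoder mirrors it. Loss weights follow the
#' reference setting `alpha = 0.1`, `gamma = 1`, `delta = 1e-4`.
#'
#' Norm convention: waveform reconstruction norms are mean squared
#' differences per element, so their weights are insensitive to segment
#' size (`norm = "sum"` switches to literal sums); the latent invariance
#' norm is always the sum over the fixed 64 dimensions.
#'
#' @param alpha invariance (intra-modal compression) weight.
#' @param gamma cross-modal cosine alignment weight.
#' @param delta cross-decoding (ECG reconstruction from radio latent) weight.
#' @param latent_dim latent size; must match the frozen ECG space.
#' @param n_voxels motion-tensor voxels fed to the model (default 64).
#' @param spatial_channels channels after the learned spatial projection.
#' @param conv_channels temporal stack widths (depth = length).
#' @param fs_hz,segment_s motion-tensor geometry (100 Hz, 10 s).
#' @param pool temporal decimation before the first convolution.
#' @param transform_strength default strength of the semantic-invariant
#'   donor transformation during training.
#' @param epochs,batch_size,lr training schedule.
#' @param weight_decay decoupled weight decay for all radio parameters
#'   (default 1e-3; the latent head sees few training subjects relative to
#'   its width and benefits from explicit shrinkage).
#' @param head_refit after gradient training, refit the linear latent head
#'   in closed form: ridge regression from the trunk+bank features to the
#'   frozen ECG targets, with the penalty chosen by subject-grouped
#'   cross-validation (segments within a subject are correlated, so
#'   pointwise criteria such as GCV badly under-penalize). Applied only
#'   when `gamma > 0` - it is the closed-form calibration of the
#'   alignment pathway. Default TRUE.
#' @param norm `"mean"` (default) or `"sum"` waveform-norm convention.
#' @param seed integer seed.
#' @return a `radio_model_config` list (with derived `model_t`).
#' @export
radio_model_config <- function(alpha = 0.1, gamma = 1, delta = 1e-4,
                               latent_dim = 64, n_voxels = 64,
                               spatial_channels = 8,
                               conv_channels = c(16, 24, 32),
                               fs_hz = 100, segment_s = 10, pool = 2,
                               transform_strength = 1,
                               epochs = 12, batch_size = 16, lr = 1e-3,
                               weight_decay = 1e-3, head_refit = TRUE,
                               norm = c("mean", "sum"), seed = 0) {
  if (alpha < 0 || gamma < 0 || delta < 0) stopf("alpha, gamma, delta must be >= 0")
  norm <- match.arg(norm)
  depth <- length(conv_channels)
  n_raw <- round(fs_hz * segment_s)
  model_t <- ((n_raw %/% pool) %/% 2^depth) * 2^depth
  structure(list(alpha = alpha, gamma = gamma, delta = delta,
                 latent_dim = latent_dim, n_voxels = n_voxels,
                 spatial_channels = spatial_channels,
                 conv_channels = conv_channels, depth = depth,
                 fs_hz = fs_hz, segment_s = segment_s, pool = pool,
                 n_raw = n_raw, model_t = model_t,
                 transform_strength = transform_strength,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay, head_refit = head_refit,
                 norm = norm, seed = seed),
            class = "radio_model_config")
}

#' Map motion-matrix segments to radio model space and back
#'
#' Model space: time-major array (segments x model_t x voxels), decimated by
#' `config$pool` and cropped to `config$model_t` frames.
#'
#' @param x motion segments: matrix (voxels x frames) or array
#'   (segments x voxels x frames).
#' @param config a [radio_model_config()].
#' @return `radio_to_model_space`: array (segments x model_t x voxels);
#'   `radio_from_model_space`: array (segments x voxels x raw frames).
#' @export
radio_to_model_space <- function(x, config) {
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  if (dim(x)[2] != config$n_voxels || dim(x)[3] != config$n_raw)
    stopf("expected %d voxels x %d frames, got %d x %d",
          config$n_voxels, config$n_raw, dim(x)[2], dim(x)[3])
  xt <- aperm(x, c(1, 3, 2))                       # (b, t, voxel)
  t2 <- dim(xt)[2] %/% config$pool
  acc <- array(0, c(dim(xt)[1], t2, dim(xt)[3]))
  for (j in seq_len(config$pool))
    acc <- acc + xt[, (seq_len(t2) - 1) * config$pool + j, , drop = FALSE]
  acc[, seq_len(config$model_t), , drop = FALSE] / config$pool
}

#' @rdname radio_to_model_space
#' @export
radio_from_model_space <- function(x, config) {
  b <- dim(x)[1]
  out <- array(0, c(b, config$n_voxels, config$n_raw))
  for (i in seq_len(b)) {
    out[i, , ] <- t(apply(x[i, , , drop = FALSE][1, , ], 2,
                          resample_linear, n_out = config$n_raw))
  }
  out
}

.radio_nets <- function(config) {
  ch <- config$conv_channels
  depth <- config$depth
  enc_layers <- list(nn_conv1d(config$n_voxels, config$spatial_channels,
                               kernel = 1, act = "linear"))
  prev <- config$spatial_channels
  for (i in seq_len(depth)) {
    enc_layers <- c(enc_layers, list(nn_conv1d(prev, ch[i], kernel = 9,
                                               stride = 2, pad = 4,
                                               act = "relu")))
    prev <- ch[i]
  }
  t_feat <- config$model_t %/% 2^depth
  enc_layers <- c(enc_layers, list(nn_flatten_gap()))
  head_layers <- list(nn_dense(t_feat * ch[depth] + ch[depth] +
                                 radio_feature_bank_dim(),
                               config$latent_dim))
  dec_layers <- list(nn_dense(config$latent_dim, t_feat * ch[depth],
                              act = "relu"),
                     nn_reshape(t_feat, ch[depth]))
  prev <- ch[depth]
  for (i in rev(seq_len(depth))) {
    out_ch <- if (i > 1) ch[i - 1] else config$spatial_channels
    dec_layers <- c(dec_layers, list(nn_upsample(2),
                                     nn_conv1d(prev, out_ch, kernel = 9,
                                               stride = 1, pad = 4,
                                               act = "relu")))
    prev <- out_ch
  }
  dec_layers <- c(dec_layers, list(nn_conv1d(prev, config$n_voxels,
                                             kernel = 1, act = "linear")))
  list(enc = nn_network(enc_layers, seed = derive_seed(config$seed, "radio-enc")),
       head = nn_network(head_layers, seed = derive_seed(config$seed, "radio-head")),
       dec = nn_network(dec_layers, seed = derive_seed(config$seed, "radio-dec")))
}

.new_radio_model <- function(config) {
  nets <- .radio_nets(config)
  nb <- radio_feature_bank_dim()
  structure(c(nets, list(config = config, frozen = FALSE, log = NULL,
                         bank_norm = list(center = numeric(nb),
                                          scale = rep(1, nb)))),
            class = "radio_model")
}

.radio_bank_scaled <- function(model, xm) {
  fb <- radio_feature_bank(xm, model$config$fs_hz / model$config$pool)
  scale(fb, center = model$bank_norm$center, scale = model$bank_norm$scale)
}

#' @export
print.radio_model <- function(x, ...) {
  cat(sprintf("<radio_model> latent %d, depth %d, alpha %g gamma %g delta %g%s\n",
              x$config$latent_dim, x$config$depth, x$config$alpha,
              x$config$gamma, x$config$delta,
              if (x$frozen) " [frozen]" else ""))
  invisible(x)
}


# ---- motion-domain feature bank --------------------------------------------

#' Fixed physiological features of a cardiac-motion segment
#'
#' Deterministic statistics of the model-space motion tensor, fed to the
#' radio encoder's latent head alongside the convolutional trunk (the head
#' mixing is fully learned - unlike the ECG side there is no frozen
#' sketch; these features merely give the encoder direct access to the
#' pulse statistics it must relate to the ECG semantic space). The bank
#' summarizes the variance-weighted mean voxel series: log band powers
#' (12 bands, 0.5-15 Hz), the beat-scale autocorrelation of the squared
#' series (lags 0.25-1.5 s), detected-pulse statistics (count, mean/SD
#' inter-pulse interval, rate, mean/SD pulse amplitude), a
#' pulse-synchronous ensemble template spanning -0.45 s to +0.45 s (which
#' carries the atrial-precursor timing and pulse width), the same template
#' normalized to unit peak plus its half-maximum width and the lag and
#' relative height of the atrial precursor (pulse-shape features that are
#' invariant to the per-subject beamformer gain), and the
#' real/imaginary Fourier coefficients of the detected-pulse impulse train
#' over 0.4-4 Hz - the beat-position block whose ECG counterpart it
#' matches up to the fixed phase rotation of the electromechanical delay.
#'
#' @param xm model-space array (segments x frames x voxels).
#' @param fs_hz model-space sampling rate.
#' @return matrix (segments x `radio_feature_bank_dim()`).
#' @export
radio_feature_bank <- function(xm, fs_hz) {
  n_seg <- dim(xm)[1]
  t_len <- dim(xm)[2]
  band_edges <- exp(seq(log(0.5), log(15), length.out = 13))
  lags <- seq(0.25, 1.5, by = 0.05)
  lag_idx <- pmin(round(lags * fs_hz), t_len - 1L)
  tmpl_off <- seq(-0.45, 0.45, length.out = 40)
  freqs <- (seq_len(t_len) - 1) / t_len * fs_hz
  f_grid <- seq(0.4, 4, by = 0.1) # matches the ECG bank's exact grid
  out <- matrix(0, n_seg, 12 + length(lags) + 6 + 40 + 43 + 2 * length(f_grid))
  for (i in seq_len(n_seg)) {
    v <- sweep(xm[i, , ], 2, colMeans(xm[i, , ]))   # frames x voxels
    # the common cardiac pulse train is a rank-1 component across voxels
    # (per-voxel gains may differ in sign through beamforming sidelobes);
    # its best estimate is the first principal component, with the global
    # sign fixed by the positive skewness of a pulse train
    sv <- svd(v, nu = 1, nv = 0)
    s <- sv$u[, 1] * sv$d[1]
    if (mean((s - mean(s))^3) < 0) s <- -s
    sc <- s - mean(s)
    spec <- Mod(stats::fft(sc))^2
    total <- sum(spec[freqs >= 0.5 & freqs <= 15]) + 1e-12
    f_spec <- log1p(vapply(seq_len(12), function(b) {
      sum(spec[freqs >= band_edges[b] & freqs < band_edges[b + 1]])
    }, numeric(1)) / total * 12)
    sq <- sc^2
    sq <- sq - mean(sq)
    ac <- as.numeric(stats::acf(sq, lag.max = max(lag_idx), plot = FALSE,
                                demean = FALSE)$acf)
    f_acf <- ac[lag_idx + 1L] / max(ac[1], 1e-12)
    pk <- .motion_peaks(s, fs_hz)
    if (length(pk) >= 3) {
      ipi <- diff(pk) / fs_hz
      amps <- s[pk]
      f_pulse <- c(length(pk) / 25, mean(ipi), min(stats::sd(ipi), 0.5),
                   0.6 / mean(ipi), mean(amps), stats::sd(amps))
      off_idx <- outer(pk, round(tmpl_off * fs_hz), "+")
      ok <- off_idx >= 1L & off_idx <= t_len
      off_idx[!ok] <- 1L
      vals <- matrix(s[off_idx], nrow = length(pk))
      vals[!ok] <- NA
      f_tmpl <- colMeans(vals, na.rm = TRUE)
      f_tmpl[!is.finite(f_tmpl)] <- 0
      # gain-invariant pulse shape: unit-peak template, half-max width,
      # atrial-precursor lag and relative height
      pkamp <- max(abs(f_tmpl))
      f_norm <- f_tmpl / max(pkamp, 1e-12)
      fwhm <- sum(f_norm > 0.5) * (tmpl_off[2] - tmpl_off[1])
      # atrial precursor: a bump on the rising shoulder of the main pulse;
      # detrend the pre-pulse window so the shoulder slope does not always
      # win the argmax
      pre_win <- which(tmpl_off >= -0.35 & tmpl_off <= -0.08)
      w <- f_norm[pre_win]
      trend <- seq(w[1], w[length(w)], length.out = length(w))
      pre_i <- which.max(w - trend)
      f_shape <- c(f_norm, fwhm, -tmpl_off[pre_win[pre_i]],
                   (w - trend)[pre_i])
    } else {
      f_pulse <- numeric(6)
      f_tmpl <- numeric(40)
      f_shape <- numeric(43)
    }
    ft <- if (length(pk) >= 3) {
      colSums(exp(-2i * pi * outer(pk / fs_hz, f_grid))) / 5
    } else rep(0i, length(f_grid))
    out[i, ] <- c(f_spec, f_acf, f_pulse, f_tmpl, f_shape, Re(ft), Im(ft))
  }
  out
}

#' @rdname radio_feature_bank
#' @export
radio_feature_bank_dim <- function() 201L

# local maxima of the cardiac-band series above an adaptive threshold,
# with a 300 ms refractory period (larger peak wins)
.motion_peaks <- function(s, fs_hz, refractory_s = 0.3) {
  n <- length(s)
  thr <- 0.4 * stats::quantile(s, 0.98, names = FALSE)
  cand <- which(s > thr & c(FALSE, diff(s) > 0) & c(diff(s) < 0, FALSE))
  if (length(cand) == 0) return(integer(0))
  keep <- integer(0)
  for (idx in cand) {
    if (length(keep) > 0 && (idx - keep[length(keep)]) / fs_hz < refractory_s) {
      if (s[idx] > s[keep[length(keep)]]) keep[length(keep)] <- idx
    } else keep <- c(keep, idx)
  }
  keep
}

# ---- semantic-invariant transformation ------------------------------------

#' Semantic-invariant donor transformation of a radio measurement
#'
#' Adds the non-cardiac component of a seeded-random donor recording to the
#' target motion segment: the donor signal with its cardiac band (default
#' 0.8-3 Hz) removed per voxel, which retains propagation-driven structure
#' (static spatial pattern, out-of-band fluctuations) while leaving the
#' target's beat-timing ground truth untouched by construction. Callers
#' must ensure the donor pool excludes the target's own subject.
#'
#' @param x motion segment, matrix (voxels x frames).
#' @param donor_pool list of motion segments (same shape) or array
#'   (n x voxels x frames).
#' @param strength scale of the added perturbation (0 = identity).
#' @param seed integer seed selecting the donor and its circular time shift.
#' @param fs_hz sampling rate of the segments (default 100).
#' @param cardiac_band band removed from the donor before mixing.
#' @return perturbed matrix, same shape as `x`.
#' @export
semantic_invariant_transform <- function(x, donor_pool, strength = 1, seed = 0,
                                         fs_hz = 100, cardiac_band = c(0.8, 3)) {
  stopifnot(is.matrix(x))
  if (strength == 0) return(x)
  if (is.array(donor_pool) && length(dim(donor_pool)) == 3) {
    donor_pool <- lapply(seq_len(dim(donor_pool)[1]),
                         function(i) donor_pool[i, , ])
  }
  if (length(donor_pool) == 0) stopf("empty donor pool")
  withr::with_seed(derive_seed(seed, "sit"), {
    donor <- donor_pool[[sample.int(length(donor_pool), 1)]]
    shift <- sample.int(ncol(donor), 1)
    donor <- donor[, c(shift:ncol(donor), seq_len(shift - 1)), drop = FALSE]
    nc <- donor
    for (v in seq_len(nrow(donor))) {
      if (all(donor[v, ] == 0)) next
      nc[v, ] <- donor[v, ] - suppress_respiration(donor[v, ], fs_hz,
                                                   band = cardiac_band)
    }
    x + strength * nc
  })
}

# ---- encode / project ------------------------------------------------------

#' Encode a radio motion measurement into semantic factors
#'
#' Deterministic projection of a motion segment into the shared 64-factor
#' semantic space (no variational posterior: the radio objective has no KL
#' term).
#'
#' @param model a `radio_model`.
#' @param x a `motion_tensor`, a motion matrix (voxels x frames), an array
#'   (segments x voxels x frames) or a model-space array.
#' @return `semantic_factors` with `mean` (segments x latent_dim),
#'   `logvar = NULL`, `modality = "RADIO"`.
#' @export
radio_encode <- function(model, x) {
  stopifnot(inherits(model, "radio_model"))
  xm <- .radio_model_input(model, x)
  h <- cbind(nn_forward(model$enc, xm)$out, .radio_bank_scaled(model, xm))
  structure(list(mean = nn_forward(model$head, h)$out, logvar = NULL,
                 modality = "RADIO", source_id = NULL),
            class = "semantic_factors")
}

.radio_model_input <- function(model, x) {
  cfg <- model$config
  if (inherits(x, "motion_tensor")) x <- motion_matrix(x)
  if (length(dim(x)) == 3 && dim(x)[2] == cfg$model_t) return(x) # model space
  radio_to_model_space(x, cfg)
}

#' Project a radio measurement into the semantic space with dual decoding
#'
#' Test-time use: radio input only. The frozen radio encoder produces the
#' semantic factors `Z_R`; the frozen ECG decoder renders the semantic ECG
#' view and the frozen radio decoder the radio view.
#'
#' @param x motion segment(s) (any form accepted by [radio_encode()]).
#' @param radio_model frozen `radio_model`.
#' @param ecg_model frozen `ecg_vae`.
#' @return list with `factors` (`semantic_factors`), `ecg_view` (segments x
#'   ECG samples, mV) and `radio_view` (segments x voxels x frames).
#' @export
project <- function(x, radio_model, ecg_model) {
  stopifnot(inherits(radio_model, "radio_model"), inherits(ecg_model, "ecg_vae"))
  if (radio_model$config$latent_dim != ecg_model$config$latent_dim)
    stopf("latent dimension mismatch between radio and ECG models")
  z <- radio_encode(radio_model, x)
  xm_hat <- nn_forward(radio_model$dec, z$mean)$out
  list(factors = z,
       ecg_view = ecg_decode(ecg_model, z$mean),
       radio_view = radio_from_model_space(xm_hat, radio_model$config))
}

# ---- loss ------------------------------------------------------------------

.sq_norm <- function(d, norm) {
  s <- rowSums(matrix(d^2, dim(d)[1]))
  if (norm == "mean") s / prod(dim(d)[-1]) else s
}

#' Arithmetic core of the radio objective
#'
#' Pure function of the tensors involved; used by [radio_loss()] and
#' directly testable with stub encoder outputs. Components (per sample,
#' averaged over the batch):
#' * `recon_radio = ||x - xhat||^2`
#' * `invariance = alpha * ||z_t - z||^2`
#' * `align = gamma * (1 - cos(z, z_e))`
#' * `recon_ecg = delta * ||x_ecg - x_ecg_hat||^2`
#'
#' @param x,xhat radio model-space arrays (b x t x voxels).
#' @param z,z_t,z_e latent matrices (b x latent_dim).
#' @param x_ecg,x_ecg_hat ECG model-space arrays (b x t x 1).
#' @param alpha,gamma,delta weights; `norm` as in [radio_model_config()].
#' @return list `total`, `recon_radio`, `invariance`, `align`, `recon_ecg`
#'   (scalars; total is their exact sum).
#' @export
radio_loss_components <- function(x, xhat, z, z_t, z_e, x_ecg, x_ecg_hat,
                                  alpha = 0.1, gamma = 1, delta = 1e-4,
                                  norm = "mean") {
  b <- nrow(z)
  recon_radio <- mean(.sq_norm(xhat - x, norm))
  zn <- sqrt(rowSums(z^2))
  en <- sqrt(rowSums(z_e^2))
  cosv <- rowSums(z * z_e) / pmax(zn * en, 1e-12)
  comp <- list(
    recon_radio = recon_radio,
    invariance = alpha * mean(rowSums((z_t - z)^2)),
    align = gamma * mean(1 - cosv),
    recon_ecg = delta * mean(.sq_norm(x_ecg_hat - x_ecg, norm))
  )
  comp$total <- comp$recon_radio + comp$invariance + comp$align + comp$recon_ecg
  comp
}

#' Evaluate the radio objective on a paired batch
#'
#' Runs the radio encoder/decoder and the frozen ECG encoder/decoder and
#' itemizes the four components of the training objective. Raises a hard
#' error if the ECG model is not frozen (its parameters must not receive
#' gradients).
#'
#' @param radio_model a `radio_model`.
#' @param ecg_model a frozen `ecg_vae`.
#' @param x radio segments (voxels x frames matrix, or segments x voxels x
#'   frames array, or model-space array).
#' @param x_ecg paired ECG segments (segments x samples, mV).
#' @param x_t transformed radio segments (same form as `x`); defaults to
#'   `x`, i.e. the identity transformation.
#' @return list of loss components (see [radio_loss_components()]).
#' @export
radio_loss <- function(radio_model, ecg_model, x, x_ecg, x_t = NULL) {
  if (!isTRUE(ecg_model$frozen))
    stopf("ECG model must be frozen before radio training (gradient isolation)")
  cfg <- radio_model$config
  xm <- .radio_model_input(radio_model, x)
  xm_t <- if (is.null(x_t)) xm else .radio_model_input(radio_model, x_t)
  z <- radio_encode(radio_model, xm)$mean
  z_t <- radio_encode(radio_model, xm_t)$mean
  z_e <- ecg_encode(ecg_model, x_ecg)$mean
  xhat <- nn_forward(radio_model$dec, z)$out
  xe_m <- if (length(dim(x_ecg)) == 3) x_ecg else
    ecg_to_model_space(x_ecg, ecg_model$config)
  xe_hat <- .ecg_dec_forward(ecg_model, z)$out
  comp <- radio_loss_components(xm, xhat, z, z_t, z_e, xe_m, xe_hat,
                                alpha = cfg$alpha, gamma = cfg$gamma,
                                delta = cfg$delta, norm = cfg$norm)
  for (nm in names(comp)) if (!is.finite(comp[[nm]]))
    stopf("NaN/Inf in loss component '%s'", nm)
  comp
}

# forward pass keeping caches for training; fb/fb_t are pre-scaled banks
.radio_forward <- function(radio_model, ecg_model, xm, xm_t, z_e, xe_m,
                           fb, fb_t) {
  cfg <- radio_model$config
  enc_f <- nn_forward(radio_model$enc, xm)
  enc_t_f <- nn_forward(radio_model$enc, xm_t)
  head_f <- nn_forward(radio_model$head, cbind(enc_f$out, fb))
  head_t_f <- nn_forward(radio_model$head, cbind(enc_t_f$out, fb_t))
  dec_f <- nn_forward(radio_model$dec, head_f$out)
  ecgdec_f <- .ecg_dec_forward(ecg_model, head_f$out)
  comp <- radio_loss_components(xm, dec_f$out, head_f$out, head_t_f$out, z_e,
                                xe_m, ecgdec_f$out,
                                alpha = cfg$alpha, gamma = cfg$gamma,
                                delta = cfg$delta, norm = cfg$norm)
  list(comp = comp, enc_f = enc_f, enc_t_f = enc_t_f, head_f = head_f,
       head_t_f = head_t_f, dec_f = dec_f, ecgdec_f = ecgdec_f,
       xm = xm, z_e = z_e, xe_m = xe_m)
}

.radio_backward <- function(radio_model, ecg_model, fw) {
  cfg <- radio_model$config
  b <- dim(fw$xm)[1]
  z <- fw$head_f$out
  z_t <- fw$head_t_f$out
  nrm_r <- if (cfg$norm == "mean") prod(dim(fw$xm)[-1]) else 1
  nrm_e <- if (cfg$norm == "mean") prod(dim(fw$xe_m)[-1]) else 1
  nrm_z <- 1 # latent invariance is always summed over dimensions

  # radio reconstruction
  dxhat <- 2 * (fw$dec_f$out - fw$xm) / (b * nrm_r)
  dec_b <- nn_backward(radio_model$dec, fw$dec_f$cache, dxhat)
  dz <- dec_b$dx
  # invariance
  dz_t <- cfg$alpha * 2 * (z_t - z) / (b * nrm_z)
  dz <- dz - dz_t
  # cosine alignment
  zn <- pmax(sqrt(rowSums(z^2)), 1e-12)
  en <- pmax(sqrt(rowSums(fw$z_e^2)), 1e-12)
  cosv <- rowSums(z * fw$z_e) / (zn * en)
  dz_cos <- -(fw$z_e / (zn * en) - cosv * z / zn^2)   # d(1-cos)/dz, row-wise
  dz <- dz + cfg$gamma * dz_cos / b
  # ECG cross-decoding through the frozen decoder (input gradient only)
  dxe <- cfg$delta * 2 * (fw$ecgdec_f$out - fw$xe_m) / (b * nrm_e)
  dz <- dz + .ecg_dec_backward(ecg_model, fw$ecgdec_f, dxe)$dz

  head_b <- nn_backward(radio_model$head, fw$head_f$cache, dz)
  head_t_b <- nn_backward(radio_model$head, fw$head_t_f$cache, dz_t)
  trunk_cols <- seq_len(ncol(fw$enc_f$out))
  enc_b <- nn_backward(radio_model$enc, fw$enc_f$cache,
                       head_b$dx[, trunk_cols, drop = FALSE])
  enc_t_b <- nn_backward(radio_model$enc, fw$enc_t_f$cache,
                         head_t_b$dx[, trunk_cols, drop = FALSE])
  list(enc = nn_add_grads(enc_b$grads, enc_t_b$grads),
       head = nn_add_grads(head_b$grads, head_t_b$grads),
       dec = dec_b$grads)
}

# ---- training --------------------------------------------------------------

#' Train and freeze the radio semantic representation model
#'
#' Optimizes the four-term objective against a frozen ECG semantic space on
#' paired radio-ECG 10-s segments. The donor transformation for the
#' invariance term is drawn per sample (seeded) from other subjects'
#' segments. The ECG model is verified frozen and its parameters are
#' untouched. Aborts at the last finite checkpoint on divergence.
#'
#' @param x_radio array (segments x voxels x frames) of motion segments.
#' @param x_ecg matrix (segments x samples, mV) of synchronized ECG.
#' @param subject_ids one id per segment (donor-pool exclusion).
#' @param ecg_model frozen `ecg_vae`.
#' @param config a [radio_model_config()].
#' @param verbose print per-epoch components.
#' @return a frozen `radio_model` with a per-epoch `log`.
#' @export
train_radio_model <- function(x_radio, x_ecg, subject_ids, ecg_model,
                              config = radio_model_config(),
                              verbose = FALSE) {
  if (!isTRUE(ecg_model$frozen))
    stopf("ECG model must be frozen before radio training (gradient isolation)")
  if (config$latent_dim != ecg_model$config$latent_dim)
    stopf("latent dimension mismatch with the frozen ECG space")
  n <- dim(x_radio)[1]
  stopifnot(length(subject_ids) == n, nrow(x_ecg) == n)
  model <- .new_radio_model(config)

  # frozen targets and inputs, computed once
  xm_all <- radio_to_model_space(x_radio, config)
  z_e_all <- ecg_encode(ecg_model, x_ecg)$mean
  xe_m_all <- ecg_to_model_space(x_ecg, ecg_model$config)

  # per-sample donor transformation (seeded, other-subject donors)
  xm_t_all <- xm_all
  if (config$alpha > 0 && config$transform_strength > 0) {
    for (i in seq_len(n)) {
      pool_idx <- which(subject_ids != subject_ids[i])
      if (length(pool_idx) == 0) stopf("empty donor pool for subject %s", subject_ids[i])
      # a small seeded candidate subset keeps the donor draw cheap
      cand <- withr::with_seed(derive_seed(config$seed, "donor-pool", i),
                               sample(pool_idx, min(4, length(pool_idx))))
      xt <- semantic_invariant_transform(
        x_radio[i, , ], lapply(cand, function(j) x_radio[j, , ]),
        strength = config$transform_strength,
        seed = derive_seed(config$seed, "donor", i), fs_hz = config$fs_hz)
      xm_t_all[i, , ] <- radio_to_model_space(xt, config)[1, , ]
    }
  }

  fb_raw <- radio_feature_bank(xm_all, config$fs_hz / config$pool)
  model$bank_norm$center <- colMeans(fb_raw)
  model$bank_norm$scale <- pmax(apply(fb_raw, 2, stats::sd), 1e-6)
  fb_all <- scale(fb_raw, center = model$bank_norm$center,
                  scale = model$bank_norm$scale)
  fb_t_all <- scale(radio_feature_bank(xm_t_all, config$fs_hz / config$pool),
                    center = model$bank_norm$center,
                    scale = model$bank_norm$scale)
  states <- list(enc = nn_adam_init(model$enc$params),
                 head = nn_adam_init(model$head$params),
                 dec = nn_adam_init(model$dec$params))
  log <- NULL
  step <- 0
  withr::with_seed(derive_seed(config$seed, "radio-train"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      comp_sum <- c(total = 0, recon_radio = 0, invariance = 0,
                    align = 0, recon_ecg = 0)
      n_batch <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        fw <- .radio_forward(model, ecg_model,
                             xm_all[idx, , , drop = FALSE],
                             xm_t_all[idx, , , drop = FALSE],
                             z_e_all[idx, , drop = FALSE],
                             xe_m_all[idx, , , drop = FALSE],
                             fb_all[idx, , drop = FALSE],
                             fb_t_all[idx, , drop = FALSE])
        if (!all(vapply(fw$comp, is.finite, logical(1)))) {
          warnf("radio training diverged at epoch %d; returning last checkpoint",
                epoch)
          model$frozen <- TRUE
          model$log <- log
          return(model)
        }
        grads <- .radio_backward(model, ecg_model, fw)
        step <- step + 1
        for (g in c("enc", "head", "dec")) {
          upd <- nn_adam_step(model[[g]]$params, grads[[g]], states[[g]],
                              lr = config$lr, t = step,
                              weight_decay = config$weight_decay %||% 0)
          model[[g]]$params <- upd$params
          states[[g]] <- upd$state
        }
        comp_sum <- comp_sum + unlist(fw$comp)[names(comp_sum)]
        n_batch <- n_batch + 1
      }
      row <- as.data.frame(as.list(comp_sum / n_batch))
      row$epoch <- epoch
      log <- rbind(log, row)
      if (verbose)
        message(sprintf("epoch %2d  total %.4f  recR %.4f  inv %.4f  align %.4f  recE %.5f",
                        epoch, row$total, row$recon_radio, row$invariance,
                        row$align, row$recon_ecg))
    }
  })
  if (isTRUE(config$head_refit) && config$gamma > 0) {
    h_tr <- cbind(nn_forward(model$enc, xm_all)$out, fb_all)
    refit <- .ridge_refit(h_tr, z_e_all, groups = subject_ids,
                          seed = derive_seed(config$seed, "refit-cv"))
    model$head$params[[1]]$W <- refit$W
    model$head$params[[1]]$b <- refit$b
  }
  model$frozen <- TRUE
  model$log <- log
  model
}

# closed-form multi-target ridge; the penalty is chosen by subject-grouped
# 4-fold cross-validation when group labels are given (falling back to the
# median grid value otherwise)
.ridge_refit <- function(h, y, lambdas = 10^seq(0, 4, by = 0.5),
                         groups = NULL, seed = 0) {
  lam <- stats::median(lambdas)
  if (!is.null(groups) && length(lambdas) > 1) {
    us <- unique(groups)
    fold <- withr::with_seed(seed, stats::setNames(
      sample(rep(1:4, length.out = length(us))), us))[groups]
    cv <- sapply(lambdas, function(l) {
      tot <- 0
      for (f in 1:4) {
        trn <- fold != f
        fit <- .ridge_solve(h[trn, , drop = FALSE], y[trn, , drop = FALSE], l)
        pred <- sweep(h[!trn, , drop = FALSE] %*% fit$W, 2, fit$b, "+")
        tot <- tot + sum((pred - y[!trn, , drop = FALSE])^2)
      }
      tot
    })
    lam <- lambdas[which.min(cv)]
  }
  out <- .ridge_solve(h, y, lam)
  out$lambda <- lam
  out
}

.ridge_solve <- function(h, y, lam) {
  ctr <- colMeans(h)
  hc <- sweep(h, 2, ctr)
  ybar <- colMeans(y)
  yc <- sweep(y, 2, ybar)
  sv <- svd(hc)
  w <- sv$v %*% ((sv$d / (sv$d^2 + lam)) * crossprod(sv$u, yc))
  list(W = w, b = as.numeric(ybar - crossprod(w, ctr)))
}
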