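# tiny paired fixtures: coupled sinusoid "motion" and "ecg" segments
tiny_paired <- function(n, rcfg, vcfg, seed = 0) {
  withr::with_seed(seed, {
    t_r <- seq(0, rcfg$segment_s, length.out = rcfg$n_raw)
    t_e <- seq(0, vcfg$segment_s, length.out = vcfg$n_raw)
    radio <- array(0, c(n, rcfg$n_voxels, rcfg$n_raw))
    ecg <- matrix(0, n, vcfg$n_raw)
    for (i in seq_len(n)) {
      f <- runif(1, 0.9, 1.8)
      pattern <- rnorm(rcfg$n_voxels, 1, 0.3)
      radio[i, , ] <- outer(pattern, sin(2 * pi * f * t_r)) +
        0.05 * matrix(rnorm(rcfg$n_voxels * rcfg$n_raw), rcfg$n_voxels)
      ecg[i, ] <- 0.8 * sin(2 * pi * f * t_e) + 0.05 * rnorm(vcfg$n_raw)
    }
    list(radio = radio, ecg = ecg,
         subjects = sprintf("S%02d", ceiling(seq_len(n) / 2)))
  })
}

test_that("semantic-invariant transform is an identity at strength 0 and seeded", {
  rcfg <- tiny_radio_config()
  pd <- tiny_paired(6, rcfg, tiny_vae_config(), seed = 1)
  x <- pd$radio[1, , ]
  pool <- lapply(3:6, function(i) pd$radio[i, , ])
  expect_identical(semantic_invariant_transform(x, pool, strength = 0), x)
  t1 <- semantic_invariant_transform(x, pool, strength = 1, seed = 5, fs_hz = 20)
  t2 <- semantic_invariant_transform(x, pool, strength = 1, seed = 5, fs_hz = 20)
  expect_identical(t1, t2)
  expect_false(identical(t1, x))
  expect_error(semantic_invariant_transform(x, list(), strength = 1), "empty donor")
})

test_that("the donor transform preserves cardiac-band content", {
  fs <- 100
  t <- (0:999) / fs
  f_beat <- 1.2
  x <- outer(rep(1, 8), sin(2 * pi * f_beat * t))
  withr::with_seed(2, {
    pool <- lapply(1:4, function(i)
      outer(rnorm(8, 1, 0.5), sin(2 * pi * 1.5 * t)) +
        0.5 * matrix(rnorm(8 * 1000), 8))
  })
  xt <- semantic_invariant_transform(x, pool, strength = 1, seed = 3, fs_hz = fs)
  band_amp <- function(sig) { # amplitude at the beat frequency
    sp <- Mod(fft(sig))
    sp[round(f_beat * length(sig) / fs) + 1]
  }
  a0 <- band_amp(x[1, ])
  a1 <- band_amp(xt[1, ])
  expect_lt(abs(a1 - a0) / a0, 0.05)
})

test_that("radio encoding is deterministic and batch-independent", {
  rcfg <- tiny_radio_config(seed = 4)
  m <- radiosem:::.new_radio_model(rcfg)
  pd <- tiny_paired(4, rcfg, tiny_vae_config(), seed = 3)
  z1 <- radio_encode(m, pd$radio)$mean
  z2 <- radio_encode(m, pd$radio)$mean
  expect_identical(z1, z2)
  expect_null(radio_encode(m, pd$radio)$logvar)
  # permuting the batch permutes outputs without cross-talk
  perm <- c(3, 1, 4, 2)
  zp <- radio_encode(m, pd$radio[perm, , ])$mean
  expect_equal(zp, z1[perm, ], tolerance = 1e-12)
  expect_error(radio_encode(m, pd$radio[, 1:5, ]), "voxels")
})

test_that("loss arithmetic matches a hand-computed oracle on fixed stubs", {
  # 1-sample stub batch, norm = "sum": every term is hand-computable
  x <- array(c(1, -1, 0.5, 0), c(1, 2, 2))
  xhat <- array(c(0.5, -0.5, 0.5, 1), c(1, 2, 2))
  z <- matrix(c(1, 0, 0), 1)
  z_t <- matrix(c(1, 0.2, 0), 1)
  z_e <- matrix(c(0, 1, 0), 1)          # orthogonal to z: cos = 0
  x_ecg <- array(c(0.2, 0.4), c(1, 2, 1))
  x_ecg_hat <- array(c(0.1, 0.1), c(1, 2, 1))
  comp <- radio_loss_components(x, xhat, z, z_t, z_e, x_ecg, x_ecg_hat,
                                alpha = 0.1, gamma = 2, delta = 1e-3,
                                norm = "sum")
  expect_equal(comp$recon_radio, 0.25 + 0.25 + 0 + 1, tolerance = 1e-9)
  expect_equal(comp$invariance, 0.1 * 0.04, tolerance = 1e-9)
  expect_equal(comp$align, 2 * 1, tolerance = 1e-9)        # gamma * (1 - 0)
  expect_equal(comp$recon_ecg, 1e-3 * (0.01 + 0.09), tolerance = 1e-9)
  expect_equal(comp$total,
               comp$recon_radio + comp$invariance + comp$align + comp$recon_ecg,
               tolerance = 1e-12)
  # parallel latents zero the alignment term
  expect_equal(radio_loss_components(x, xhat, z, z, 3 * z, x_ecg, x_ecg_hat,
                                     gamma = 1, norm = "sum")$align, 0,
               tolerance = 1e-12)
  # identity transformation zeroes the invariance term
  expect_equal(comp$invariance * 0,
               radio_loss_components(x, xhat, z, z, z_e, x_ecg, x_ecg_hat,
                                     norm = "sum")$invariance)
})

test_that("radio training demands a frozen ECG model and leaves it untouched", {
  rcfg <- tiny_radio_config(seed = 5, epochs = 2)
  vcfg <- tiny_vae_config(seed = 5)
  pd <- tiny_paired(8, rcfg, vcfg, seed = 4)
  unfrozen <- radiosem:::.new_ecg_vae(vcfg)
  expect_error(train_radio_model(pd$radio, pd$ecg, pd$subjects, unfrozen, rcfg),
               "frozen")
  ecg_m <- train_ecg_vae(pd$ecg, NULL, vcfg)
  before <- ecg_m[c("enc", "dec")]
  rm1 <- train_radio_model(pd$radio, pd$ecg, pd$subjects, ecg_m, rcfg)
  expect_identical(ecg_m[c("enc", "dec")], before) # gradient isolation
  expect_true(rm1$frozen)
  expect_true(all(is.finite(as.matrix(rm1$log[, 1:5]))))
  expect_lt(rm1$log$total[nrow(rm1$log)], rm1$log$total[1])
  # determinism of the whole training
  rm2 <- train_radio_model(pd$radio, pd$ecg, pd$subjects, ecg_m, rcfg)
  expect_identical(rm1$enc$params, rm2$enc$params)
})

test_that("projection decodes both modalities deterministically", {
  rcfg <- tiny_radio_config(seed = 6, epochs = 2)
  vcfg <- tiny_vae_config(seed = 6)
  pd <- tiny_paired(8, rcfg, vcfg, seed = 5)
  ecg_m <- train_ecg_vae(pd$ecg, NULL, vcfg)
  rm <- train_radio_model(pd$radio, pd$ecg, pd$subjects, ecg_m, rcfg)
  p1 <- project(pd$radio[1, , ], rm, ecg_m)
  p2 <- project(pd$radio[1, , ], rm, ecg_m)
  expect_identical(p1$factors$mean, p2$factors$mean)
  expect_equal(dim(p1$ecg_view), c(1, vcfg$n_raw))
  expect_equal(dim(p1$radio_view), c(1, rcfg$n_voxels, rcfg$n_raw))
  # latent mismatch between the two frozen models errors
  bad <- rm
  bad$config$latent_dim <- 5
  expect_error(project(pd$radio[1, , ], bad, ecg_m), "latent dimension")
})
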