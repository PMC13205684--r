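test_that("mu-law compander is odd, monotone, endpoint-exact and invertible", {
  expect_identical(mulaw_encode(0), 0)
  expect_equal(mulaw_encode(1, mu = 255), 1)
  expect_equal(mulaw_encode(-1, mu = 255), -1)
  withr::with_seed(1, x <- runif(1000, -1, 1))
  expect_equal(mulaw_decode(mulaw_encode(x)), x, tolerance = 1e-12)
  expect_equal(mulaw_encode(-x), -mulaw_encode(x)) # odd
  xs <- sort(x)
  expect_true(all(diff(mulaw_encode(xs)) > 0))     # strictly monotone
  expect_warning(mulaw_encode(1.5), "clipped")
})

test_that("diagonal-Gaussian KL matches closed forms and Monte Carlo", {
  # prior posterior: zero divergence
  expect_equal(kl_diag_gaussian(rep(0, 8), rep(0, 8)), 0)
  # 1-D N(1, 1) || N(0, 1): (mu^2 + sigma^2 - 1 - log sigma^2)/2 = 0.5
  expect_equal(kl_diag_gaussian(1, 0), 0.5)
  expect_true(all(kl_diag_gaussian(matrix(rnorm(50), 10),
                                   matrix(rnorm(50), 10)) >= 0))
  # Monte-Carlo oracle: E_q[log q - log p] over 1e5 samples
  withr::with_seed(7, {
    mu <- rnorm(4)
    lv <- rnorm(4, 0, 0.5)
    n <- 1e5
    zs <- matrix(rnorm(n * 4), n, 4)
    zs <- sweep(sweep(zs, 2, exp(0.5 * lv), "*"), 2, mu, "+")
    logq <- -0.5 * rowSums(sweep(sweep(zs, 2, mu)^2, 2, exp(lv), "/") +
                             matrix(lv + log(2 * pi), n, 4, byrow = TRUE))
    logp <- -0.5 * rowSums(zs^2 + log(2 * pi))
    mc <- logq - logp
    se <- sd(mc) / sqrt(n)
    expect_lt(abs(mean(mc) - kl_diag_gaussian(mu, lv)), 3 * se)
  })
})

test_that("reparameterized posterior sampling is centred on the mean", {
  f <- structure(list(mean = matrix(c(0.5, -1, 2), 1),
                      logvar = matrix(c(0, -1, 0.5), 1), modality = "ECG"),
                 class = "semantic_factors")
  s <- ecg_sample_posterior(f, 10000, seed = 2)
  se <- exp(0.5 * f$logvar[1, ]) / sqrt(10000)
  expect_true(all(abs(colMeans(s) - f$mean[1, ]) < 3 * se))
})

test_that("encoding is deterministic and shape-checked", {
  cfg <- tiny_vae_config(seed = 5)
  m <- radiosem:::.new_ecg_vae(cfg)
  x <- tiny_segments(3, cfg, seed = 1)
  f1 <- ecg_encode(m, x)
  f2 <- ecg_encode(m, x)
  expect_identical(f1$mean, f2$mean)
  expect_equal(dim(f1$mean), c(3, cfg$latent_dim))
  # identical segments produce identical posteriors
  xx <- rbind(x[1, ], x[1, ])
  ff <- ecg_encode(m, xx)
  expect_equal(ff$mean[1, ], ff$mean[2, ])
  expect_error(ecg_encode(m, x[, 1:50]), "samples per segment")
  expect_error(ecg_decode(m, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("the objective decomposes and flags non-finite components", {
  cfg <- tiny_vae_config(seed = 6, beta = 0.7, lambda_sup = 0.3)
  m <- radiosem:::.new_ecg_vae(cfg)
  x <- tiny_segments(4, cfg, seed = 2)
  loss <- ecg_loss(m, x, labels = c("NORMAL", "AF", "PB", "AF"))
  expect_equal(loss$total, loss$recon + 0.7 * loss$kl + 0.3 * loss$sup,
               tolerance = 1e-12)
  expect_gte(loss$kl, 0)
  # without labels the supervised term is skipped
  l2 <- ecg_loss(m, x)
  expect_identical(l2$sup, 0)
})

test_that("short training reduces the loss deterministically", {
  cfg <- tiny_vae_config(seed = 8, epochs = 6)
  x <- tiny_segments(16, cfg, seed = 3)
  labels <- rep(c("NORMAL", "AF"), 8)
  m1 <- train_ecg_vae(x, labels, cfg)
  expect_true(m1$frozen)
  expect_lt(m1$log$total[nrow(m1$log)], m1$log$total[1])
  m2 <- train_ecg_vae(x, labels, cfg)
  expect_identical(m1$enc$params, m2$enc$params) # same data + seed -> same fit
  expect_identical(m1$dec$params, m2$dec$params)
})

test_that("removing the KL penalty frees reconstruction capacity", {
  # the constraint must bind measurably at this tiny scale, so the
  # constrained run uses a clearly non-zero KL weight
  x <- tiny_segments(16, tiny_vae_config(), seed = 4)
  m_b0 <- train_ecg_vae(x, NULL, tiny_vae_config(seed = 9, beta = 0, epochs = 25))
  m_b2 <- train_ecg_vae(x, NULL, tiny_vae_config(seed = 9, beta = 5, epochs = 25))
  expect_lte(m_b0$log$recon[nrow(m_b0$log)], m_b2$log$recon[nrow(m_b2$log)])
  expect_lt(m_b2$log$kl[nrow(m_b2$log)], m_b0$log$kl[nrow(m_b0$log)])
})

test_that("autoencoding a single repeated template converges", {
  cfg <- tiny_vae_config(seed = 10, epochs = 60, beta = 0.01,
                         lambda_sup = 0, batch_size = 4, lr = 3e-3)
  t <- seq(0, 10, length.out = cfg$n_raw)
  template <- matrix(0.8 * sin(2 * pi * 0.9 * t), 1)
  m <- train_ecg_vae(template[rep(1, 12), ], NULL, cfg)
  z <- ecg_encode(m, template)
  # the likelihood lives in companded model space: near-perfect there
  xm_hat <- nn_forward(m$dec, z$mean)$out
  xm <- ecg_to_model_space(template, cfg)
  expect_gt(cor(as.vector(xm_hat), as.vector(xm)), 0.95)
  # mu-law expansion amplifies residuals on the raw scale
  expect_gt(cor(ecg_decode(m, z)[1, ], template[1, ]), 0.9)
})

test_that("checkpoints round-trip through save/load", {
  cfg <- tiny_vae_config(seed = 11)
  m <- radiosem:::.new_ecg_vae(cfg)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$enc$params, m$enc$params)
  x <- tiny_segments(1, cfg, seed = 6)
  expect_identical(ecg_encode(m, x)$mean, ecg_encode(m2, x)$mean)
})
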