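test_that("noiseless linear targets are recovered exactly", {
  withr::with_seed(40, {
    z <- matrix(rnorm(200 * 8), 200)
    w <- rnorm(8)
    y <- drop(z %*% w) + 2.5
  })
  ro <- fit_linear_readout(z, y)
  expect_equal(unname(ro$weights[-1, 1]), w, tolerance = 1e-8)
  expect_equal(unname(ro$weights[1, 1]), 2.5, tolerance = 1e-8)
  expect_gt(cor(predict_readout(ro, z)[, 1], y), 1 - 1e-10)
})

test_that("permuted labels yield near-zero held-out correlation", {
  withr::with_seed(41, {
    z <- matrix(rnorm(500 * 8), 500)
    y <- sample(rnorm(500)) # independent of z
  })
  ro <- fit_linear_readout(z[1:250, ], y[1:250])
  r <- cor(predict_readout(ro, z[251:500, ])[, 1], y[251:500])
  expect_lt(abs(r), 0.2)
})

test_that("prediction is the documented affine map", {
  ro <- structure(list(weights = matrix(c(3, rep(0, 4)), 5,
                                        dimnames = list(NULL, "t")),
                       target_names = "t", fit_metadata = list()),
                  class = "linear_readout")
  z <- matrix(rnorm(12), 3)
  expect_equal(unname(predict_readout(ro, z)[, 1]), rep(3, 3)) # intercept only
  ro$weights[2, 1] <- 2 # one active factor
  expect_equal(unname(predict_readout(ro, z)[, 1]), 3 + 2 * z[, 1])
  # adding a zero-weight factor never changes predictions
  ro2 <- ro
  ro2$weights <- rbind(ro$weights, 0)
  expect_equal(predict_readout(ro2, cbind(z, rnorm(3))),
               predict_readout(ro, z))
})

test_that("ridge fallback engages for degenerate designs", {
  withr::with_seed(42, z <- matrix(rnorm(5 * 8), 5)) # n < factors
  ro <- fit_linear_readout(z, rnorm(5))
  expect_true(ro$fit_metadata$ridge)
  expect_true(all(is.finite(ro$weights)))
})

test_that("readout evaluation refuses overlapping subjects across folds", {
  withr::with_seed(43, z <- matrix(rnorm(40 * 4), 40))
  subj <- rep(c("A", "B", "C", "D"), each = 10)
  ro <- fit_linear_readout(z[1:20, ], rnorm(20), subject_ids = subj[1:20])
  expect_error(predict_readout(ro, z[11:30, ], subject_ids = subj[11:30]),
               "leakage")
  expect_silent(predict_readout(ro, z[21:40, ], subject_ids = subj[21:40]))
})

test_that("linearly separable factors give a perfect training fit", {
  withr::with_seed(44, {
    z <- rbind(matrix(rnorm(60 * 4, 0), 60),
               matrix(rnorm(60 * 4, 4), 60),
               matrix(rnorm(60 * 4, -4), 60))
  })
  labels <- rep(c("NORMAL", "AF", "PB"), each = 60)
  dm <- fit_diagnosis(z, labels)
  out <- predict_diagnosis(dm, z, recording_ids = seq_len(180))
  expect_equal(f1_score(out$class, labels[order(order(out$recording))], "AF"), 1)
  expect_error(fit_diagnosis(z[1:60, ], labels[1:60]), "single-class")
})

test_that("recording aggregation is the mean-probability rule", {
  # three segments with AF probabilities 0.9 / 0.8 / 0.1 -> mean 0.6 -> called
  withr::with_seed(45, {
    ztr <- rbind(matrix(rnorm(80 * 2, -2), 80), matrix(rnorm(80 * 2, 2), 80))
    labtr <- rep(c("NORMAL", "AF"), each = 80)
  })
  dm <- fit_diagnosis(ztr, labtr)
  # construct test factors whose segment probabilities bracket the threshold
  target_p <- function(p) { # find a point on the decision axis with P(AF)=p
    co <- coef(dm$fit)
    a <- co[1]; b <- co[2:3]
    lo <- (log(p / (1 - p)) - a) / sum(b^2)
    matrix(lo * b, 1)
  }
  zte <- rbind(target_p(0.9), target_p(0.8), target_p(0.1))
  out <- predict_diagnosis(dm, zte, recording_ids = rep("R1", 3))
  expect_equal(out$AF, 0.6, tolerance = 0.02)
  expect_equal(out$class, "AF")
  att <- diagnosis_attribution(dm)
  expect_equal(dim(att), c(1, 2)) # one non-reference class x two factors
})

test_that("top-correlated factor identification honors ties and constants", {
  withr::with_seed(46, {
    z <- matrix(rnorm(100 * 10), 100)
    y <- z[, 7] + 0.01 * rnorm(100)
  })
  tc <- top_correlated_factor(z, y)
  expect_equal(tc$index, 7)
  expect_gt(abs(tc$correlation), 0.99)
  # constant factors are excluded from the argmax
  z[, 7] <- 5
  tc2 <- top_correlated_factor(z, y)
  expect_false(tc2$index == 7)
  expect_error(top_correlated_factor(z[1:2, ], y[1:2]), "n >= 3")
})

test_that("readout JSON serialization round-trips predictions", {
  withr::with_seed(47, {
    z <- matrix(rnorm(50 * 4), 50)
    y <- cbind(hr = rnorm(50), qt = rnorm(50))
  })
  ro <- fit_linear_readout(z, y)
  path <- withr::local_tempfile(fileext = ".json")
  save_model_json(ro, path)
  ro2 <- load_readout_json(path)
  expect_equal(predict_readout(ro2, z), predict_readout(ro, z),
               tolerance = 1e-12)
})
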