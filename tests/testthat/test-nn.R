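test_that("backpropagated gradients match finite differences", {
  net <- nn_network(list(
    nn_conv1d(2, 3, kernel = 3, stride = 2, pad = 1, act = "relu"),
    nn_pool(2), nn_upsample(2),
    nn_conv1d(3, 2, kernel = 3, stride = 1, pad = 1, act = "tanh"),
    nn_flatten(), nn_dense(12, 4, act = "tanh"), nn_dense(4, 2)), seed = 7)
  withr::with_seed(42, {
    x <- array(rnorm(2 * 12 * 2), c(2, 12, 2))
    tgt <- matrix(rnorm(4), 2)
  })
  lossf <- function(n) {
    o <- nn_forward(n, x)$out
    0.5 * sum((o - tgt)^2)
  }
  fw <- nn_forward(net, x)
  bw <- nn_backward(net, fw$cache, fw$out - tgt)
  for (li in seq_along(net$params)) {
    if (is.null(net$params[[li]])) next
    for (pn in c("W", "b")) {
      f <- function(v) {
        n2 <- net
        n2$params[[li]][[pn]][] <- v
        lossf(n2)
      }
      ng <- num_grad(f, as.vector(net$params[[li]][[pn]]))
      ag <- as.vector(bw$grads[[li]][[pn]])
      expect_lt(max(abs(ng - ag)) / max(1e-8, max(abs(ng))), 1e-6)
    }
  }
  fx <- function(v) {
    x2 <- x
    x2[] <- v
    o <- nn_forward(net, x2)$out
    0.5 * sum((o - tgt)^2)
  }
  ngx <- num_grad(fx, as.vector(x))
  expect_lt(max(abs(ngx - as.vector(bw$dx))) / max(abs(ngx)), 1e-6)
})

test_that("layer shapes compose as specified", {
  net <- nn_network(list(nn_conv1d(3, 5, kernel = 9, stride = 2, pad = 4),
                         nn_pool(2), nn_upsample(4), nn_flatten()), seed = 1)
  x <- array(0, c(4, 32, 3))
  out <- nn_forward(net, x)$out
  # 32 -> 16 (stride 2, same pad) -> 8 (pool) -> 32 (upsample) -> 32*5 flat
  expect_equal(dim(out), c(4, 160))
  expect_error(nn_forward(net, array(0, c(4, 32, 2))), "channels")
})

test_that("initialization and Adam updates are deterministic given seeds", {
  layers <- list(nn_dense(6, 4, act = "relu"), nn_dense(4, 2))
  n1 <- nn_network(layers, seed = 3)
  n2 <- nn_network(layers, seed = 3)
  expect_identical(n1$params, n2$params)
  expect_false(identical(nn_network(layers, seed = 4)$params, n1$params))
  withr::with_seed(1, {
    x <- matrix(rnorm(12), 2)
    y <- matrix(rnorm(4), 2)
  })
  run <- function(net) {
    st <- nn_adam_init(net$params)
    for (t in 1:5) {
      fw <- nn_forward(net, x)
      bw <- nn_backward(net, fw$cache, fw$out - y)
      upd <- nn_adam_step(net$params, bw$grads, st, lr = 1e-2, t = t)
      net$params <- upd$params
      st <- upd$state
    }
    net$params
  }
  expect_identical(run(n1), run(n2))
})

test_that("gradient clipping preserves direction and caps the global norm", {
  net <- nn_network(list(nn_dense(3, 2)), seed = 1)
  g <- list(list(W = matrix(30, 3, 2), b = rep(40, 2)))
  st <- nn_adam_init(net$params)
  # one step with huge gradients must not explode the parameters
  upd <- nn_adam_step(net$params, g, st, lr = 0.1, t = 1, clip = 1)
  expect_true(all(abs(upd$params[[1]]$W - net$params[[1]]$W) <= 0.1 + 1e-12))
})
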