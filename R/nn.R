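## Minimal neural-network layer library.
##
## Self-contained dense / 1D-convolution stacks with manual backpropagation
## and an Adam optimizer, written against base-R matrix algebra (BLAS).
## Sequence data flow through layers as (batch, time, channel) arrays; dense
## layers operate on (batch, feature) matrices. Gradients are exercised
## against finite differences in the test suite.

#' Layer constructors for [nn_network()]
#'
#' * `nn_dense(n_in, n_out, act)` - affine map with optional nonlinearity.
#' * `nn_conv1d(in_ch, out_ch, kernel, stride, pad, act)` - 1D convolution
#'   over the time axis (im2col implementation).
#' * `nn_pool(factor)` - fixed average pooling over time.
#' * `nn_upsample(factor)` - nearest-neighbour repetition over time.
#' * `nn_flatten(t, ch)` / `nn_reshape(t, ch)` - move between array and
#'   matrix views.
#'
#' @param n_in,n_out,in_ch,out_ch,kernel,stride,pad,factor,t,ch integer sizes.
#' @param act one of `"linear"`, `"relu"`, `"tanh"`.
#' @return a layer specification list.
#' @name nn_layers
NULL

#' @rdname nn_layers
#' @export
nn_dense <- function(n_in, n_out, act = "linear") {
  list(type = "dense", n_in = n_in, n_out = n_out, act = act)
}

#' @rdname nn_layers
#' @export
nn_conv1d <- function(in_ch, out_ch, kernel, stride = 1, pad = 0,
                      act = "linear") {
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       stride = stride, pad = pad, act = act)
}

#' @rdname nn_layers
#' @export
nn_pool <- function(factor) list(type = "pool", factor = factor)

#' @rdname nn_layers
#' @export
nn_upsample <- function(factor) list(type = "upsample", factor = factor)

#' @rdname nn_layers
#' @export
nn_flatten <- function() list(type = "flatten")

#' @rdname nn_layers
#' @export
nn_flatten_gap <- function() list(type = "flatten_gap")

#' @rdname nn_layers
#' @export
nn_reshape <- function(t, ch) list(type = "reshape", t = t, ch = ch)

#' Assemble a network from layer specifications and initialize parameters
#'
#' Weights use He initialization for ReLU layers and Xavier otherwise;
#' biases start at zero. Deterministic given the seed.
#'
#' @param layers list of layer specs from the `nn_*` constructors.
#' @param seed integer seed.
#' @return a `nn_network` list with `$layers` and `$params`.
#' @export
nn_network <- function(layers, seed = 0) {
  params <- withr::with_seed(derive_seed(seed, "nn-init"), {
    lapply(layers, function(l) {
      if (l$type == "dense") {
        fan_in <- l$n_in
        sdv <- if (identical(l$act, "relu")) sqrt(2 / fan_in) else sqrt(1 / fan_in)
        list(W = matrix(stats::rnorm(l$n_in * l$n_out, 0, sdv), l$n_in, l$n_out),
             b = numeric(l$n_out))
      } else if (l$type == "conv1d") {
        fan_in <- l$kernel * l$in_ch
        sdv <- if (identical(l$act, "relu")) sqrt(2 / fan_in) else sqrt(1 / fan_in)
        list(W = matrix(stats::rnorm(fan_in * l$out_ch, 0, sdv), fan_in, l$out_ch),
             b = numeric(l$out_ch))
      } else NULL
    })
  })
  structure(list(layers = layers, params = params), class = "nn_network")
}

.nn_act <- function(x, act) {
  switch(act, linear = x, relu = pmax(x, 0), tanh = tanh(x),
         stopf("unknown activation '%s'", act))
}

.nn_act_grad <- function(out, act) {
  switch(act, linear = 1, relu = (out > 0) * 1, tanh = 1 - out^2)
}

#' Forward pass through a network
#'
#' @param net a `nn_network`.
#' @param x input: matrix (batch x features) or array (batch x time x ch).
#' @return list with `out` and per-layer `cache` for [nn_backward()].
#' @export
nn_forward <- function(net, x) {
  cache <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    p <- net$params[[i]]
    if (l$type == "dense") {
      out <- sweep(x %*% p$W, 2, p$b, "+")
      out <- .nn_act(out, l$act)
      cache[[i]] <- list(x = x, out = out)
    } else if (l$type == "conv1d") {
      fw <- .conv1d_forward(x, p, l)
      out <- fw$out
      cache[[i]] <- fw$cache
    } else if (l$type == "pool") {
      d <- dim(x)
      t2 <- d[2] %/% l$factor
      acc <- array(0, c(d[1], t2, d[3]))
      for (j in seq_len(l$factor)) {
        acc <- acc + x[, (seq_len(t2) - 1) * l$factor + j, , drop = FALSE]
      }
      out <- acc / l$factor
      cache[[i]] <- list(dim_in = d)
    } else if (l$type == "upsample") {
      d <- dim(x)
      out <- x[, rep(seq_len(d[2]), each = l$factor), , drop = FALSE]
      cache[[i]] <- list(dim_in = d)
    } else if (l$type == "flatten") {
      d <- dim(x)
      out <- x
      dim(out) <- c(d[1], d[2] * d[3])
      cache[[i]] <- list(dim_in = d)
    } else if (l$type == "flatten_gap") {
      # flattened features followed by per-channel global time-averages,
      # giving downstream heads shift-invariant rate/shape statistics
      d <- dim(x)
      flat <- x
      dim(flat) <- c(d[1], d[2] * d[3])
      gap <- apply(x, c(1, 3), mean)
      if (is.null(dim(gap))) gap <- matrix(gap, d[1])
      out <- cbind(flat, gap)
      cache[[i]] <- list(dim_in = d)
    } else if (l$type == "reshape") {
      out <- x
      dim(out) <- c(nrow(x), l$t, l$ch)
      cache[[i]] <- list(dim_in = dim(x))
    } else stopf("unknown layer type '%s'", l$type)
    x <- out
  }
  list(out = x, cache = cache)
}

.conv1d_forward <- function(x, p, l) {
  d <- dim(x)
  b <- d[1]; t_in <- d[2]; ch <- d[3]
  if (ch != l$in_ch) stopf("conv1d: expected %d channels, got %d", l$in_ch, ch)
  tp <- t_in + 2L * l$pad
  lout <- (tp - l$kernel) %/% l$stride + 1L
  col <- .conv1d_im2col(x, l$kernel, l$stride, l$pad) # (b*lout, kernel*ch)
  out <- sweep(col %*% p$W, 2, p$b, "+")
  out <- .nn_act(out, l$act)
  outa <- out
  dim(outa) <- c(b, lout, l$out_ch)
  list(out = outa,
       cache = list(col = col, out = out, dim_in = d, tp = tp, lout = lout))
}

#' Backward pass: gradients of a scalar loss w.r.t. parameters and input
#'
#' @param net a `nn_network`.
#' @param cache the cache returned by [nn_forward()].
#' @param dout gradient of the loss w.r.t. the network output.
#' @return list with `grads` (per layer, `W`/`b` or NULL) and `dx`.
#' @export
nn_backward <- function(net, cache, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    p <- net$params[[i]]
    cc <- cache[[i]]
    if (l$type == "dense") {
      dz <- dout * .nn_act_grad(cc$out, l$act)
      grads[[i]] <- list(W = crossprod(cc$x, dz), b = colSums(dz))
      dout <- tcrossprod(dz, p$W)
    } else if (l$type == "conv1d") {
      d <- cc$dim_in
      b <- d[1]
      dym <- dout
      dim(dym) <- c(b * cc$lout, l$out_ch)
      dym <- dym * .nn_act_grad(cc$out, l$act)
      grads[[i]] <- list(W = crossprod(cc$col, dym), b = colSums(dym))
      dcol <- tcrossprod(dym, p$W)             # (b*lout, kernel*ch)
      dout <- .conv1d_col2im(dcol, b, d[2], l$in_ch,
                             l$kernel, l$stride, l$pad)
    } else if (l$type == "pool") {
      d <- cc$dim_in
      t2 <- d[2] %/% l$factor
      dx <- array(0, d)
      for (j in seq_len(l$factor)) {
        dx[, (seq_len(t2) - 1L) * l$factor + j, ] <- dout / l$factor
      }
      dout <- dx
    } else if (l$type == "upsample") {
      d <- cc$dim_in
      dx <- array(0, d)
      for (j in seq_len(l$factor)) {
        dx <- dx + dout[, (seq_len(d[2]) - 1L) * l$factor + j, , drop = FALSE]
      }
      dout <- dx
    } else if (l$type == "flatten") {
      dim(dout) <- cc$dim_in
    } else if (l$type == "flatten_gap") {
      d <- cc$dim_in
      dflat <- dout[, seq_len(d[2] * d[3]), drop = FALSE]
      dgap <- dout[, d[2] * d[3] + seq_len(d[3]), drop = FALSE]
      dim(dflat) <- d
      # spread the pooled gradient uniformly over time
      spread <- array(rep(dgap / d[2], each = 1), c(d[1], d[3], d[2]))
      dout <- dflat + aperm(spread, c(1, 3, 2))
    } else if (l$type == "reshape") {
      dim(dout) <- cc$dim_in
    }
  }
  list(grads = grads, dx = dout)
}

#' Adam optimizer state and update
#'
#' `nn_adam_init` builds first/second-moment accumulators matching a
#' parameter list; `nn_adam_step` applies one bias-corrected Adam update
#' (optionally with global gradient-norm clipping) and returns updated
#' params and state.
#'
#' @param params,grads,state nested lists as produced by [nn_network()] /
#'   [nn_backward()] / `nn_adam_init`.
#' @param lr learning rate.
#' @param t step counter (1-based).
#' @param beta1,beta2,eps Adam constants.
#' @param clip global gradient-norm ceiling (NULL to disable).
#' @param weight_decay decoupled (AdamW-style) weight decay on W (default 0).
#' @return `nn_adam_init`: a state list. `nn_adam_step`: list with updated
#'   `params` and `state`.
#' @export
nn_adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

#' @rdname nn_adam_init
#' @export
nn_adam_step <- function(params, grads, state, lr = 1e-3, t = 1,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = 5,
                         weight_decay = 0) {
  if (!is.null(clip)) {
    sq <- sum(vapply(grads, function(g) {
      if (is.null(g)) 0 else sum(g$W^2) + sum(g$b^2)
    }, numeric(1)))
    nrm <- sqrt(sq)
    if (is.finite(nrm) && nrm > clip) {
      scl <- clip / nrm
      grads <- lapply(grads, function(g) {
        if (is.null(g)) NULL else list(W = g$W * scl, b = g$b * scl)
      })
    }
  }
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^t
    c2 <- 1 - beta2^t
    params[[i]]$W <- params[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps) -
      lr * weight_decay * params[[i]]$W
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}

# element-wise addition of two gradient lists (accumulating encoder passes)
nn_add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    a[[i]]$W <- a[[i]]$W + b[[i]]$W
    a[[i]]$b <- a[[i]]$b + b[[i]]$b
  }
  a
}
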