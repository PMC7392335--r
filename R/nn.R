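## Minimal layer zoo with manual backpropagation.
##
## Activations are L x C matrices (rows = positions); a batch is a list of
## such matrices. Convolutions run through the compiled kernels in
## src/conv_ops.cpp; batch normalization pools statistics across the whole
## batch. Each layer_*_fwd returns list(out, cache); each layer_*_bwd takes
## the upstream gradient list and returns list(dx, grads).

new_conv <- function(c_in, c_out, k, dilation = 1L) {
  # fan-in scaled (He) initialization; caller controls the RNG state
  sd <- sqrt(2 / (c_in * k))
  list(type = "conv",
       W = matrix(rnorm(c_out * c_in * k, 0, sd), nrow = c_out),
       b = numeric(c_out), c_in = c_in, c_out = c_out, k = as.integer(k),
       dilation = as.integer(dilation))
}

new_bn <- function(c, momentum = 0.99, eps = 1e-3) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       momentum = momentum, eps = eps)
}

new_act <- function() list(type = "gelu")

# fused batch-norm + GELU (the bn->gelu pair of tower/final blocks);
# backward recomputes intermediates from the cached layer input
new_bn_gelu <- function(c, momentum = 0.99, eps = 1e-3) {
  list(type = "bn_gelu", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       momentum = momentum, eps = eps)
}
new_pool <- function() list(type = "maxpool")
new_dropout <- function(p) list(type = "dropout", p = p)
new_residual <- function(layers) list(type = "residual", layers = layers)

nn_forward <- function(layers, xs, training = FALSE) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    res <- switch(lay$type,
      conv = list(out = conv1d_fwd_batch(xs, lay$W, lay$b,
                                         lay$dilation),
                  cache = xs),
      bn = bn_fwd(lay, xs, training),
      bn_gelu = bn_gelu_fwd(lay, xs, training),
      gelu = list(out = lapply(xs, gelu_fwd_c), cache = xs),
      maxpool = pool_fwd(xs),
      dropout = {
        if (training && lay$p > 0) {
          masks <- lapply(xs, function(x)
            dropout_mask_c(nrow(x), ncol(x), lay$p))
          list(out = Map(`*`, xs, masks), cache = masks)
        } else list(out = xs, cache = NULL)
      },
      residual = {
        sub <- nn_forward(lay$layers, xs, training)
        list(out = Map(`+`, xs, sub$out), cache = sub$caches)
      },
      softplus = list(out = lapply(xs, softplus_fwd_c), cache = xs),
      stop2("unknown layer type ", lay$type))
    caches[li] <- list(res$cache)   # not [[<-]]: cache may be NULL
    xs <- res$out
  }
  list(out = xs, caches = caches)
}

# returns list(dx = grads w.r.t. input batch, grads = per-layer parameter
# gradients parallel to `layers`)
nn_backward <- function(layers, caches, dys) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    lay <- layers[[li]]
    cache <- caches[[li]]
    res <- switch(lay$type,
      conv = {
        bw <- conv1d_bwd_batch(cache, lay$W, dys, lay$dilation)
        list(dx = bw$dX, grads = list(W = bw$dW, b = bw$db))
      },
      bn = bn_bwd(lay, cache, dys),
      bn_gelu = bn_gelu_bwd(lay, cache, dys),
      gelu = list(dx = Map(gelu_bwd_c, cache, dys), grads = NULL),
      maxpool = pool_bwd(cache, dys),
      dropout = {
        if (is.null(cache)) list(dx = dys, grads = NULL)
        else list(dx = Map(`*`, dys, cache), grads = NULL)
      },
      residual = {
        sub <- nn_backward(lay$layers, cache, dys)
        list(dx = Map(`+`, dys, sub$dx),
             grads = list(layers = sub$grads))
      },
      softplus = list(dx = Map(softplus_bwd_c, cache, dys),
                      grads = NULL))
    grads[li] <- list(res$grads)    # not [[<-]]: grads may be NULL
    dys <- res$dx
  }
  list(dx = dys, grads = grads)
}

bn_fwd <- function(lay, xs, training) {
  if (training) {
    n <- sum(vapply(xs, nrow, 1L))
    stats <- lapply(xs, bn_stats_c)
    s <- Reduce(`+`, lapply(stats, `[[`, "s"))
    sq <- Reduce(`+`, lapply(stats, `[[`, "sq"))
    mu <- as.numeric(s) / n
    v <- pmax(as.numeric(sq) / n - mu^2, 0)
  } else {
    mu <- lay$run_mean
    v <- lay$run_var
  }
  std <- sqrt(v + lay$eps)
  applied <- lapply(xs, bn_apply_c, mu = mu, invstd = 1 / std,
                    gamma = lay$gamma, beta = lay$beta)
  xhat <- lapply(applied, `[[`, "xhat")
  out <- lapply(applied, `[[`, "out")
  cache <- list(xhat = xhat, std = std, mu = mu, v = v,
                training = training)
  list(out = out, cache = cache)
}

bn_bwd <- function(lay, cache, dys) {
  xhat <- cache$xhat
  dgamma <- Reduce(`+`, Map(function(xh, dy) colSums(xh * dy), xhat, dys))
  dbeta <- Reduce(`+`, lapply(dys, colSums))
  coef <- lay$gamma / cache$std
  if (!cache$training) {
    # inference mode: running statistics are constants
    zero <- numeric(length(coef))
    dx <- Map(function(xh, dy) bn_bwd_c(xh, dy, zero, zero, coef),
              xhat, dys)
    return(list(dx = dx, grads = list(gamma = dgamma, beta = dbeta)))
  }
  n <- sum(vapply(dys, nrow, 1L))
  dx <- Map(function(xh, dy)
    bn_bwd_c(xh, dy, dbeta / n, dgamma / n, coef), xhat, dys)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

bn_gelu_fwd <- function(lay, xs, training) {
  if (training) {
    n <- sum(vapply(xs, nrow, 1L))
    stats <- lapply(xs, bn_stats_c)
    mu <- as.numeric(Reduce(`+`, lapply(stats, `[[`, "s"))) / n
    v <- pmax(as.numeric(Reduce(`+`, lapply(stats, `[[`, "sq"))) / n -
                mu^2, 0)
  } else {
    mu <- lay$run_mean
    v <- lay$run_var
  }
  invstd <- 1 / sqrt(v + lay$eps)
  out <- lapply(xs, bn_gelu_fwd_c, mu = mu, invstd = invstd,
                gamma = lay$gamma, beta = lay$beta)
  list(out = out,
       cache = list(x = xs, mu = mu, v = v, invstd = invstd,
                    training = training))
}

bn_gelu_bwd <- function(lay, cache, dys) {
  part <- Map(function(x, dy)
    bn_gelu_bwd_partial_c(x, dy, cache$mu, cache$invstd, lay$gamma,
                          lay$beta), cache$x, dys)
  sum_dg <- as.numeric(Reduce(`+`, lapply(part, `[[`, "sum_dg")))
  sum_dgxh <- as.numeric(Reduce(`+`, lapply(part, `[[`, "sum_dgxh")))
  n <- sum(vapply(dys, nrow, 1L))
  dx <- Map(function(x, dy)
    bn_gelu_bwd_c(x, dy, cache$mu, cache$invstd, lay$gamma, lay$beta,
                  sum_dg / n, sum_dgxh / n, cache$training),
    cache$x, dys)
  list(dx = dx, grads = list(gamma = sum_dgxh, beta = sum_dg))
}

# bn running-statistics refresh, applied after each optimizer step
bn_update_run <- function(lay, cache) {
  m <- lay$momentum
  lay$run_mean <- m * lay$run_mean + (1 - m) * cache$mu
  lay$run_var <- m * lay$run_var + (1 - m) * cache$v
  lay
}

pool_fwd <- function(xs) {
  res <- lapply(xs, pool2_fwd_c)
  list(out = lapply(res, `[[`, "out"),
       cache = lapply(res, `[[`, "sel"))
}

pool_bwd <- function(sels, dys) {
  list(dx = Map(pool2_bwd_c, sels, dys), grads = NULL)
}

## parameter bookkeeping -----------------------------------------------

# map over (layers, grads) pairs applying f(param, grad) to every numeric
# parameter; returns updated layers. `state` is a parallel structure for
# momentum buffers (created on first use).
PARAM_FIELDS <- list(conv = c("W", "b"), bn = c("gamma", "beta"),
                     bn_gelu = c("gamma", "beta"))

sgd_update <- function(layers, grads, state, lr, momentum, scale = 1) {
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    g <- grads[[li]]
    if (is.null(g)) next
    if (lay$type == "residual") {
      sub <- sgd_update(lay$layers, g$layers,
                        state[[li]] %||% vector("list",
                                                length(lay$layers)),
                        lr, momentum, scale)
      layers[[li]]$layers <- sub$layers
      state[[li]] <- sub$state
      next
    }
    fields <- PARAM_FIELDS[[lay$type]]
    st <- state[[li]] %||% list()
    for (f in fields) {
      vel <- st[[f]] %||% (g[[f]] * 0)
      vel <- momentum * vel - lr * g[[f]] * scale
      st[[f]] <- vel
      layers[[li]][[f]] <- lay[[f]] + vel
    }
    state[[li]] <- st
  }
  list(layers = layers, state = state)
}

# refresh bn running stats from this batch's caches
bn_refresh <- function(layers, caches) {
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    if (lay$type %in% c("bn", "bn_gelu") &&
        isTRUE(caches[[li]]$training)) {
      layers[[li]] <- bn_update_run(lay, caches[[li]])
    } else if (lay$type == "residual") {
      layers[[li]]$layers <- bn_refresh(lay$layers, caches[[li]])
    }
  }
  layers
}
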