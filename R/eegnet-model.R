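## EEGNet-style compact CNN, implemented from first principles.
##
## The network operates on inputs of shape [batch, channels, samples] and is
## internally expressed as 1-D convolutions along time (Rcpp kernels) plus
## matrix products:
##   block 1: shared temporal conv (F1 filters, no bias, same-padding) ->
##            batchnorm -> depthwise spatial conv collapsing the channel axis
##            (D filters per temporal map, max-norm 1, no bias) -> batchnorm
##            -> ELU -> mean/max pool (1,4) -> dropout
##   block 2: separable conv = depthwise temporal conv (per map, same-padding)
##            + pointwise 1x1 mixing to F2 maps -> batchnorm -> ELU ->
##            pool (1,8) -> dropout
##   block 3: classifier conv spanning the remaining time steps -> log-softmax.
##
## Even kernels are padded floor(k/2) on both sides and the trailing extra
## output column is cropped, so "same" length is preserved exactly.
## Batch normalization uses the statistics of the batch being processed in
## both training and evaluation (no running buffers), making evaluation a
## pure deterministic function of the weights and the evaluated batch.
## Reshapes between layers use in-place `dim<-` wherever the tensor is
## single-referenced; batchnorm/ELU run in fused C++ loops.

BN_EPS <- 1e-5

#' Initialize an EEGNet model
#'
#' Creates the model with Xavier-uniform convolution weights (bounds
#' `sqrt(6 / (fan_in + fan_out))` with the usual convolution fan convention),
#' batchnorm scale 1 / shift 0 and zero classifier bias. Deterministic given
#' `seed`.
#'
#' @param config An [eegnet_config()].
#' @param seed RNG seed for the weight draw.
#' @return An object of class `eegnet`.
#' @examples
#' m <- eegnet_init(eegnet_config(10, n_channels = 8), seed = 1)
#' summary(m)
#' @export
eegnet_init <- function(config, seed = 1) {
  stopifnot(inherits(config, "eegnet_config"))
  C <- config$n_channels
  F1 <- config$F1
  M <- config$F1 * config$D
  F2 <- config$F2
  k1 <- config$kernel1
  k2 <- config$kernel2
  t2 <- config$t2
  N <- config$n_classes
  xavier <- function(dim, fan_in, fan_out) {
    b <- sqrt(6 / (fan_in + fan_out))
    array(runif(prod(dim), -b, b), dim)
  }
  params <- with_seed_local(seed, list(
    # temporal conv, weight tensor [F1, 1, 1, k1]
    W1 = xavier(c(k1, F1), fan_in = k1, fan_out = F1 * k1),
    gamma1 = rep(1, F1), beta1 = rep(0, F1),
    # depthwise spatial conv, weight tensor [M, 1, C, 1]
    W2 = xavier(c(M, C), fan_in = C, fan_out = M * C),
    gamma2 = rep(1, M), beta2 = rep(0, M),
    # separable depthwise temporal conv, weight tensor [M, 1, 1, k2]
    W3 = xavier(c(k2, M), fan_in = k2, fan_out = M * k2),
    # pointwise 1x1 conv, weight tensor [F2, M, 1, 1]
    W4 = xavier(c(F2, M), fan_in = M, fan_out = F2),
    gamma3 = rep(1, F2), beta3 = rep(0, F2),
    # classifier conv, weight tensor [N, F2, 1, t2]; flattened (t, f) t-fastest
    W5 = xavier(c(N, t2 * F2), fan_in = F2 * t2, fan_out = N * t2),
    b5 = rep(0, N)
  ))
  structure(list(config = config, params = params), class = "eegnet")
}

#' @export
print.eegnet <- function(x, ...) {
  print(x$config)
  cat(sprintf("  total trainable parameters: %d\n", eegnet_n_params(x)))
  invisible(x)
}

#' @export
summary.eegnet <- function(object, ...) {
  eegnet_shapes(object$config)
}

#' Total trainable parameter count
#' @param model An `eegnet` model.
#' @return Integer.
#' @export
eegnet_n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Project max-norm-constrained filters back onto the unit ball
#'
#' The depthwise spatial filters carry a maximum-norm constraint: after every
#' optimizer step, any filter whose L2 norm over input channels exceeds
#' `max_norm` is rescaled to that norm; filters inside the ball are left
#' untouched.
#'
#' @param model An `eegnet` model.
#' @param max_norm The norm bound (default from the config, 1).
#' @return The model with projected spatial filters.
#' @export
apply_max_norm <- function(model, max_norm = model$config$max_norm) {
  norms <- sqrt(rowSums(model$params$W2^2))
  over <- norms > max_norm
  if (any(over)) {
    model$params$W2[over, ] <- model$params$W2[over, , drop = FALSE] *
      (max_norm / norms[over])
  }
  model
}

## ---------------------------------------------------------------------------
## forward / backward

bn_fwd <- function(x, gamma, beta) {
  res <- bn_fwd2_cpp(x, gamma, beta, BN_EPS)
  res$x <- x # reference only; z is recomputed in the backward kernel
  res
}
bn_bwd <- function(dy, cache, gamma) {
  bn_bwd2_cpp(dy, cache$x, cache$mu, cache$istd, gamma)
}

## pool along the time axis: x is a [T0, cols] matrix
pool_fwd <- function(x, T0, width, type) {
  t_out <- T0 %/% width
  xc <- x[seq_len(width * t_out), , drop = FALSE]
  dim(xc) <- c(width, t_out * ncol(x))
  if (type == "mean") {
    out <- .colMeans(xc, width, ncol(xc))
    dim(out) <- c(t_out, ncol(x))
    list(out = out, argmax = NULL)
  } else {
    am <- max.col(t(xc), ties.method = "first")
    out <- xc[cbind(am, seq_along(am))]
    dim(out) <- c(t_out, ncol(x))
    list(out = out, argmax = am)
  }
}

pool_bwd <- function(dy, T0, width, type, argmax = NULL) {
  t_out <- nrow(dy)
  cols <- ncol(dy)
  dx <- matrix(0, T0, cols)
  if (type == "mean") {
    dx[seq_len(width * t_out), ] <- dy[rep(seq_len(t_out), each = width), ] / width
  } else {
    dgrp <- matrix(0, width, t_out * cols)
    dgrp[cbind(argmax, seq_along(argmax))] <- as.vector(dy)
    dim(dgrp) <- c(width * t_out, cols)
    dx[seq_len(width * t_out), ] <- dgrp
  }
  dx
}

pad_time <- function(x, p) {
  if (p == 0) {
    return(x)
  }
  rbind(matrix(0, p, ncol(x)), x, matrix(0, p, ncol(x)))
}

## forward pass; x is [B, C, T]. Returns log-probabilities [B, N] and,
## if keep_cache, every intermediate needed for backprop.
eegnet_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- dim(x)
  B <- d[1]
  C <- cfg$n_channels
  T0 <- cfg$n_samples
  if (d[2] != C || d[3] != T0) {
    abort(sprintf(
      "input is [%d, %d, %d] but the model expects [B, %d, %d].",
      d[1], d[2], d[3], C, T0
    ))
  }
  M <- cfg$F1 * cfg$D

  ## block 1: temporal conv over every (batch, channel) series
  x1 <- aperm(x, c(3, 1, 2))
  dim(x1) <- c(T0, B * C) # columns ordered batch-fastest
  xp1 <- pad_time(x1, cfg$kernel1 %/% 2L)
  y1 <- conv1d_fwd(xp1, p$W1, T0) # [T, B*C, F1]
  dim(y1) <- c(T0 * B * C, cfg$F1)
  bn1 <- bn_fwd(y1, p$gamma1, p$beta1)

  ## depthwise spatial conv: collapse the channel axis
  a <- bn1$out
  bn1$out <- NULL
  dim(a) <- c(T0 * B, C, cfg$F1)
  z <- matrix(0, T0 * B, M)
  for (f in seq_len(cfg$F1)) {
    rows <- (f - 1L) * cfg$D + seq_len(cfg$D)
    z[, rows] <- a[, , f] %*% t(p$W2[rows, , drop = FALSE])
  }
  bn2 <- bn_fwd(z, p$gamma2, p$beta2)
  act1 <- elu_cpp(bn2$out) # [T*B, M]
  bn2$out <- NULL
  pool1 <- pool_fwd(matrix(act1, T0, B * M), T0, 4L, cfg$pooling)
  t1 <- cfg$t1
  drop1 <- dropout_fwd(pool1$out, cfg$dropout, training)

  ## block 2: separable conv (depthwise temporal + pointwise)
  xp2 <- pad_time(drop1$out, cfg$kernel2 %/% 2L) # [t1 + 2p, B*M]
  map <- rep(seq_len(M), each = B)
  y2 <- dwconv1d_fwd(xp2, p$W3, map, t1) # [t1, B*M]
  u <- matrix(y2, t1 * B, M) %*% t(p$W4) # [t1*B, F2]
  bn3 <- bn_fwd(u, p$gamma3, p$beta3)
  act2 <- elu_cpp(bn3$out)
  bn3$out <- NULL
  pool2 <- pool_fwd(matrix(act2, t1, B * cfg$F2), t1, 8L, cfg$pooling)
  t2 <- cfg$t2
  drop2 <- dropout_fwd(pool2$out, cfg$dropout, training)

  ## block 3: classifier over the flattened (time, map) features
  fl <- matrix(aperm(array(drop2$out, c(t2, B, cfg$F2)), c(1, 3, 2)), t2 * cfg$F2, B)
  logits <- p$W5 %*% fl + p$b5 # [N, B]
  mx <- apply(logits, 2, max)
  lse <- mx + log(colSums(exp(sweep(logits, 2, mx))))
  logp <- sweep(logits, 2, lse)

  cache <- NULL
  if (keep_cache) {
    cache <- list(
      B = B, xp1 = xp1, bn1 = bn1, a = a, bn2 = bn2, act1 = act1,
      pool1 = pool1, drop1 = drop1, xp2 = xp2, map = map, y2 = y2,
      bn3 = bn3, act2 = act2, pool2 = pool2, drop2 = drop2, fl = fl
    )
  }
  list(
    logp = t(logp), # [B, N]
    shapes = list(
      block1 = c(B, M, 1, t1), block2 = c(B, cfg$F2, 1, t2),
      out = c(B, cfg$n_classes)
    ),
    cache = cache
  )
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- (matrix(runif(length(x)), nrow(x), ncol(x)) >= p) / (1 - p)
  list(out = x * mask, mask = mask)
}

## backward pass from dlogits [N, B]; returns gradients named as the params
eegnet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  B <- cache$B
  C <- cfg$n_channels
  T0 <- cfg$n_samples
  M <- cfg$F1 * cfg$D
  t1 <- cfg$t1
  t2 <- cfg$t2

  ## block 3
  dW5 <- dlogits %*% t(cache$fl)
  db5 <- rowSums(dlogits)
  dfl <- t(p$W5) %*% dlogits # [t2*F2, B]
  dim(dfl) <- c(t2, cfg$F2, B)
  ddrop2 <- aperm(dfl, c(1, 3, 2))
  dim(ddrop2) <- c(t2, B * cfg$F2)

  ## block 2 backward
  dpool2 <- if (is.null(cache$drop2$mask)) ddrop2 else ddrop2 * cache$drop2$mask
  dact2 <- pool_bwd(dpool2, t1, 8L, cfg$pooling, cache$pool2$argmax)
  dim(dact2) <- c(t1 * B, cfg$F2)
  dbn3out <- elu_bwd_cpp(dact2, cache$act2)
  bn3b <- bn_bwd(dbn3out, cache$bn3, p$gamma3)
  du <- bn3b$dx # [t1*B, F2]
  dW4 <- t(du) %*% matrix(cache$y2, t1 * B, M)
  dy2 <- du %*% p$W4
  dim(dy2) <- c(t1, B * M)
  p2 <- cfg$kernel2 %/% 2L
  dW3 <- dwconv1d_bwd_w(dy2, cache$xp2, cache$map, cfg$kernel2, M)
  dxp2 <- dwconv1d_bwd_x(dy2, p$W3, cache$map, nrow(cache$xp2))
  ddrop1 <- dxp2[p2 + seq_len(t1), , drop = FALSE]

  ## block 1 backward
  dpool1 <- if (is.null(cache$drop1$mask)) ddrop1 else ddrop1 * cache$drop1$mask
  dact1 <- pool_bwd(dpool1, T0, 4L, cfg$pooling, cache$pool1$argmax)
  dim(dact1) <- c(T0 * B, M)
  dbn2out <- elu_bwd_cpp(dact1, cache$act1)
  bn2b <- bn_bwd(dbn2out, cache$bn2, p$gamma2)
  dz <- bn2b$dx # [T*B, M]
  dW2 <- matrix(0, M, C)
  da <- array(0, c(T0 * B, C, cfg$F1))
  for (f in seq_len(cfg$F1)) {
    rows <- (f - 1L) * cfg$D + seq_len(cfg$D)
    dW2[rows, ] <- t(dz[, rows, drop = FALSE]) %*% cache$a[, , f]
    da[, , f] <- dz[, rows, drop = FALSE] %*% p$W2[rows, , drop = FALSE]
  }
  dim(da) <- c(T0 * B * C, cfg$F1)
  bn1b <- bn_bwd(da, cache$bn1, p$gamma1)
  dy1 <- bn1b$dx
  bn1b$dx <- NULL
  dim(dy1) <- c(T0, B * C, cfg$F1)
  dW1 <- conv1d_bwd_w(dy1, cache$xp1, cfg$kernel1)

  list(
    W1 = dW1, gamma1 = bn1b$dgamma, beta1 = bn1b$dbeta,
    W2 = dW2, gamma2 = bn2b$dgamma, beta2 = bn2b$dbeta,
    W3 = dW3, W4 = dW4, gamma3 = bn3b$dgamma, beta3 = bn3b$dbeta,
    W5 = dW5, b5 = db5
  )
}

#' Predict from a fitted EEGNet
#'
#' Evaluation-mode forward pass (dropout off; batch normalization uses the
#' statistics of the supplied batch, so predictions are a deterministic
#' function of the weights and the batch).
#'
#' @param object An `eegnet` model.
#' @param x Input array `[n, channels, samples]` or a `fnirs_windows` whose
#'   channel count matches the model.
#' @param type `"class"` (factor of predicted labels), `"prob"` or
#'   `"logprob"` (n x classes matrices).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.eegnet <- function(object, x, type = c("class", "prob", "logprob"), ...) {
  type <- match.arg(type)
  if (inherits(x, "fnirs_windows")) x <- x$windows
  lp <- eegnet_forward(object, x, training = FALSE)$logp
  colnames(lp) <- TASK_LEVELS[seq_len(object$config$n_classes)]
  switch(type,
    logprob = lp,
    prob = exp(lp),
    class = factor(colnames(lp)[max.col(lp, ties.method = "first")],
      levels = colnames(lp)
    )
  )
}
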