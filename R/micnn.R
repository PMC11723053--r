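# Compact multi-kernel depthwise-separable 1D CNN for epoched EEG/EOG.
#
# Architecture (time axis only, input depth = channels):
#   [optional channel attention] ->
#   three parallel temporal convolutions (kernels 3/5/9, length-preserving
#   padding, filters_per_kernel maps each) -> concatenation (96 maps at the
#   defaults) -> ReLU -> batch norm -> depthwise convolution (kernel 25,
#   padding 7, one filter per map: length L-10) -> depthwise-separable
#   convolution (depthwise kernel 25 pad 7 + pointwise 1x1) -> batch norm
#   -> ELU -> average pooling -> dropout -> flatten -> dense -> logits.
#
# Forward and backward passes are written out explicitly (the grouped
# convolutions in C, the rest in R); a finite-difference gradient check in
# the test suite is the correctness oracle.

#' Model configuration for the compact EEG/EOG CNN
#'
#' @param n_channels,n_samples,n_classes input dimensions.
#' @param temporal_kernels kernel sizes of the parallel temporal
#'   convolutions (default `c(3, 5, 9)`: small kernels catch localized
#'   features, larger ones broader structure).
#' @param filters_per_kernel maps per temporal kernel (default 32; the
#'   three defaults concatenate to 96 maps).
#' @param depthwise_kernel,depthwise_padding kernel and symmetric padding
#'   of the two depthwise stages (defaults 25 and 7: each stage shortens
#'   the time axis by `kernel - 1 - 2*padding = 10` samples).
#' @param pool_size average-pooling width and stride (default 8).
#' @param dropout dropout rate in [0, 1) applied after pooling.
#' @param attention include the channel-attention front end?
#' @param attention_reduction reduction ratio r of the attention
#'   bottleneck (gate convolutions map C -> ceiling(C/r) -> C).
#' @param bn_after_activation keep the stated order ReLU-then-batch-norm
#'   after the temporal block (`TRUE`, default); `FALSE` swaps to the
#'   BN-then-activation convention.
#' @return object of class `micnn_config`.
#' @export
micnn_config <- function(n_channels, n_samples, n_classes,
                         temporal_kernels = c(3L, 5L, 9L),
                         filters_per_kernel = 32L,
                         depthwise_kernel = 25L,
                         depthwise_padding = 7L,
                         pool_size = 8L,
                         dropout = 0.5,
                         attention = FALSE,
                         attention_reduction = 4L,
                         bn_after_activation = TRUE) {
  cfg <- list(n_channels = as.integer(n_channels),
              n_samples = as.integer(n_samples),
              n_classes = as.integer(n_classes),
              temporal_kernels = as.integer(temporal_kernels),
              filters_per_kernel = as.integer(filters_per_kernel),
              depthwise_kernel = as.integer(depthwise_kernel),
              depthwise_padding = as.integer(depthwise_padding),
              pool_size = as.integer(pool_size),
              dropout = dropout,
              attention = isTRUE(attention),
              attention_reduction = as.integer(attention_reduction),
              bn_after_activation = isTRUE(bn_after_activation))
  cfg$n_maps <- cfg$filters_per_kernel * length(cfg$temporal_kernels)
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop2("dropout must be in [0, 1)")
  if (cfg$attention_reduction < 1L) stop2("attention_reduction must be >= 1")
  class(cfg) <- "micnn_config"
  micnn_shapes(cfg)  # validates that every stage keeps length >= 1
  cfg
}

#' Per-stage output shapes of a model configuration
#'
#' Audits the architecture arithmetic: maps and time length after each
#' stage. Errors (naming the stage) if any stage's output length would
#' fall below 1.
#'
#' @param config a [micnn_config()].
#' @return data frame with columns `stage`, `maps`, `length`.
#' @export
micnn_shapes <- function(config) {
  L <- config$n_samples
  M <- config$n_maps
  dk <- config$depthwise_kernel
  dp <- config$depthwise_padding
  shrink <- dk - 1L - 2L * dp
  stages <- list(c("input", config$n_channels, L))
  if (config$attention)
    stages <- c(stages, list(c("channel_attention", config$n_channels, L)))
  L1 <- L - shrink
  L2 <- L1 - shrink
  L3 <- L2 %/% config$pool_size
  stages <- c(stages, list(
    c("temporal_concat", M, L),
    c("depthwise", M, L1),
    c("separable", M, L2),
    c("avg_pool", M, L3),
    c("flatten", 1L, M * L3),
    c("dense", 1L, config$n_classes)))
  df <- data.frame(stage = vapply(stages, `[`, "", 1L),
                   maps = as.integer(vapply(stages, `[`, "", 2L)),
                   length = as.integer(vapply(stages, `[`, "", 3L)))
  bad <- which(df$length < 1L)
  if (length(bad))
    stop2("n_samples = ", config$n_samples, " too short: stage '",
          df$stage[bad[1L]], "' would have length ", df$length[bad[1L]])
  df
}

attention_width <- function(config) {
  max(1L, as.integer(ceiling(config$n_channels / config$attention_reduction)))
}

#' Build (initialize) a model from a configuration
#'
#' Weight initialization is He-style Gaussian scaled by fan-in; biases are
#' zero; batch-norm scale/shift start at 1/0 with unit running variance.
#' Depthwise stages carry no bias (convention).
#'
#' @param config a [micnn_config()].
#' @param seed optional integer seed for the initialization draw.
#' @return object of class `micnn_model`: `config`, `params` (named list
#'   of arrays), `bn_run` (running batch-norm statistics).
#' @export
micnn_build <- function(config, seed = NULL) {
  C <- config$n_channels; M <- config$n_maps
  Fk <- config$filters_per_kernel; dk <- config$depthwise_kernel
  K <- config$n_classes
  D <- M * micnn_shapes(config)$length[match("avg_pool", micnn_shapes(config)$stage)]
  he <- function(dims, fan_in) array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
  with_seed(seed, {
    params <- list()
    if (config$attention) {
      Cr <- attention_width(config)
      # first gate conv random, second zero: all gates start at sigmoid(0)
      # = 0.5 and move only under consistent loss pressure, so gate values
      # track channel usefulness rather than initialization noise
      params$aw1 <- matrix(rnorm(Cr * C, sd = sqrt(1 / C)), Cr, C)
      params$ab1 <- numeric(Cr)
      params$aw2 <- matrix(0, C, Cr)
      params$ab2 <- numeric(C)
    }
    for (i in seq_along(config$temporal_kernels)) {
      k <- config$temporal_kernels[i]
      params[[paste0("tw", i)]] <- he(c(Fk, C, k), C * k)
      params[[paste0("tb", i)]] <- numeric(Fk)
    }
    params$bn1_g <- rep(1, M); params$bn1_b <- numeric(M)
    params$dw1 <- he(c(M, 1L, dk), dk)
    params$sdw <- he(c(M, 1L, dk), dk)
    params$spw <- he(c(M, M, 1L), M)
    params$spw_b <- numeric(M)
    params$bn2_g <- rep(1, M); params$bn2_b <- numeric(M)
    params$fc_w <- matrix(rnorm(K * D, sd = sqrt(2 / D)), K, D)
    params$fc_b <- numeric(K)
    structure(list(config = config, params = params,
                   bn_run = list(m1 = numeric(M), v1 = rep(1, M),
                                 m2 = numeric(M), v2 = rep(1, M))),
              class = "micnn_model")
  })
}

#' Number of trainable parameters
#'
#' @param model a `micnn_model` or fitted [micnn()] object.
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- layer primitives ------------------------------------------------------

slice_map <- function(x, j) matrix(x[, j, ], nrow = dim(x)[1L])

bn_forward <- function(x, gamma, beta, run_m, run_v, training,
                       eps = 1e-5, momentum = 0.1) {
  M <- dim(x)[2L]
  y <- x
  xhat <- x
  invstd <- numeric(M)
  for (j in seq_len(M)) {
    xj <- slice_map(x, j)
    if (training) {
      mu <- mean(xj)
      v <- mean((xj - mu)^2)
      run_m[j] <- (1 - momentum) * run_m[j] + momentum * mu
      run_v[j] <- (1 - momentum) * run_v[j] + momentum * v
    } else {
      mu <- run_m[j]; v <- run_v[j]
    }
    invstd[j] <- 1 / sqrt(v + eps)
    xh <- (xj - mu) * invstd[j]
    xhat[, j, ] <- xh
    y[, j, ] <- gamma[j] * xh + beta[j]
  }
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       run_m = run_m, run_v = run_v)
}

bn_backward <- function(dy, cache) {
  M <- dim(dy)[2L]
  dx <- dy
  dgamma <- numeric(M); dbeta <- numeric(M)
  for (j in seq_len(M)) {
    dyj <- slice_map(dy, j)
    xh <- slice_map(cache$xhat, j)
    dgamma[j] <- sum(dyj * xh)
    dbeta[j] <- sum(dyj)
    dxh <- dyj * cache$gamma[j]
    dx[, j, ] <- cache$invstd[j] * (dxh - mean(dxh) - xh * mean(dxh * xh))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

avgpool_forward <- function(x, p) {
  d <- dim(x)
  L3 <- d[3L] %/% p
  out <- array(0, c(d[1L], d[2L], L3))
  base <- (seq_len(L3) - 1L) * p
  for (j in seq_len(p)) out <- out + x[, , base + j, drop = FALSE]
  out / p
}

avgpool_backward <- function(dout, p, L_in) {
  d <- dim(dout)
  dx <- array(0, c(d[1L], d[2L], L_in))
  base <- (seq_len(d[3L]) - 1L) * p
  for (j in seq_len(p)) dx[, , base + j] <- dout / p
  dx
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

# ---- channel attention -----------------------------------------------------

attention_stage <- function(params, x) {
  d <- dim(x)
  N <- d[1L]; C <- d[2L]; L <- d[3L]
  ap <- matrix(0, N, C); mp <- matrix(0, N, C)
  amax <- matrix(1L, N, C)
  for (c in seq_len(C)) {
    xc <- slice_map(x, c)
    ap[, c] <- rowMeans(xc)
    amax[, c] <- max.col(xc, ties.method = "first")
    mp[, c] <- xc[cbind(seq_len(N), amax[, c])]
  }
  u <- ap %*% t(params$aw1) + rep(params$ab1, each = N)
  v <- mp %*% t(params$aw1) + rep(params$ab1, each = N)
  ur <- pmax(u, 0); vr <- pmax(v, 0)
  za <- ur %*% t(params$aw2) + rep(params$ab2, each = N)
  zm <- vr %*% t(params$aw2) + rep(params$ab2, each = N)
  g <- 1 / (1 + exp(-(za + zm)))
  y <- x * as.vector(g)  # [N,C] broadcasts over the L axis
  list(y = y, gates = g,
       cache = list(x = x, ap = ap, mp = mp, amax = amax,
                    u = u, v = v, ur = ur, vr = vr, g = g))
}

attention_backward <- function(params, cache, dy) {
  d <- dim(dy)
  N <- d[1L]; C <- d[2L]; L <- d[3L]
  g <- cache$g
  dg <- matrix(0, N, C)
  dx <- dy * as.vector(g)
  for (c in seq_len(C))
    dg[, c] <- rowSums(slice_map(dy, c) * slice_map(cache$x, c))
  ds <- dg * g * (1 - g)          # shared by the avg and max paths
  dur <- ds %*% params$aw2
  dvr <- dur                       # same downstream weights
  daw2 <- t(ds) %*% cache$ur + t(ds) %*% cache$vr
  dab2 <- 2 * colSums(ds)
  du <- dur * (cache$u > 0)
  dv <- dvr * (cache$v > 0)
  daw1 <- t(du) %*% cache$ap + t(dv) %*% cache$mp
  dab1 <- colSums(du) + colSums(dv)
  dap <- du %*% params$aw1
  dmp <- dv %*% params$aw1
  for (c in seq_len(C)) {
    dx[, c, ] <- dx[, c, ] + dap[, c] / L
    idx <- cbind(seq_len(N), rep(c, N), cache$amax[, c])
    dx[idx] <- dx[idx] + dmp[, c]
  }
  list(dx = dx, daw1 = daw1, dab1 = dab1, daw2 = daw2, dab2 = dab2)
}

#' Channel-attention front end: gated batch and gate values
#'
#' Applies the model's channel-attention stage to a trial batch: adaptive
#' average and max pooling collapse the time axis, each pooled vector
#' passes through the shared bottleneck (C -> C/r -> C) with ReLU between,
#' the two paths are summed and sigmoid-squashed into per-channel gates in
#' (0, 1), and the input is scaled channel-wise by its gate.
#'
#' @param model a `micnn_model` or fitted [micnn()] with
#'   `config$attention = TRUE`. (Raw arrays expected; a fitted model's
#'   stored normalization is NOT applied here.)
#' @param x numeric array `n_trials x n_channels x n_samples`.
#' @return list with `gated` (same shape as `x`) and `gates`
#'   (`n_trials x n_channels`, all in (0, 1)).
#' @export
attention_forward <- function(model, x) {
  if (!isTRUE(model$config$attention))
    stop2("model was built without the channel-attention front end")
  st <- attention_stage(model$params, x)
  list(gated = st$y, gates = st$gates)
}

# ---- full forward / backward ----------------------------------------------

micnn_forward <- function(model, x, training = FALSE, drop_mask = NULL) {
  cfg <- model$config
  p <- model$params
  cache <- list()
  bn_run <- model$bn_run

  if (cfg$attention) {
    st <- attention_stage(p, x)
    cache$att <- st$cache
    x <- st$y
  }
  cache$x_in <- x

  maps <- vector("list", length(cfg$temporal_kernels))
  for (i in seq_along(cfg$temporal_kernels)) {
    k <- cfg$temporal_kernels[i]
    pl <- (k - 1L) %/% 2L
    maps[[i]] <- .conv1d_fwd(x, p[[paste0("tw", i)]], p[[paste0("tb", i)]],
                             pl, k - 1L - pl, 1L)
  }
  tc <- array(0, c(dim(x)[1L], cfg$n_maps, cfg$n_samples))
  off <- 0L
  for (i in seq_along(maps)) {
    tc[, off + seq_len(cfg$filters_per_kernel), ] <- maps[[i]]
    off <- off + cfg$filters_per_kernel
  }

  if (cfg$bn_after_activation) {
    cache$relu_in <- tc
    a <- pmax(tc, 0)
    bn1 <- bn_forward(a, p$bn1_g, p$bn1_b, bn_run$m1, bn_run$v1, training)
    cache$bn1 <- bn1$cache
    h <- bn1$y
  } else {
    bn1 <- bn_forward(tc, p$bn1_g, p$bn1_b, bn_run$m1, bn_run$v1, training)
    cache$bn1 <- bn1$cache
    cache$relu_in <- bn1$y
    h <- pmax(bn1$y, 0)
  }
  bn_run$m1 <- bn1$run_m; bn_run$v1 <- bn1$run_v
  cache$dw1_in <- h

  dp <- cfg$depthwise_padding
  d1 <- .conv1d_fwd(h, p$dw1, numeric(0), dp, dp, cfg$n_maps)
  cache$sdw_in <- d1
  d2 <- .conv1d_fwd(d1, p$sdw, numeric(0), dp, dp, cfg$n_maps)
  cache$spw_in <- d2
  s <- .conv1d_fwd(d2, p$spw, p$spw_b, 0L, 0L, 1L)

  bn2 <- bn_forward(s, p$bn2_g, p$bn2_b, bn_run$m2, bn_run$v2, training)
  cache$bn2 <- bn2$cache
  bn_run$m2 <- bn2$run_m; bn_run$v2 <- bn2$run_v
  cache$elu_in <- bn2$y
  e <- elu(bn2$y)
  cache$pool_in_len <- dim(e)[3L]
  pl <- avgpool_forward(e, cfg$pool_size)

  if (training && cfg$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- array((runif(length(pl)) >= cfg$dropout) / (1 - cfg$dropout),
                         dim(pl))
    pl <- pl * drop_mask
  }
  cache$drop_mask <- drop_mask
  cache$flat_dim <- dim(pl)
  flat <- matrix(pl, nrow = dim(pl)[1L])
  cache$flat <- flat
  logits <- flat %*% t(p$fc_w) + rep(p$fc_b, each = nrow(flat))
  list(logits = logits, cache = cache, bn_run = bn_run)
}

micnn_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  g <- list()

  g$fc_w <- t(dlogits) %*% cache$flat
  g$fc_b <- colSums(dlogits)
  dflat <- dlogits %*% p$fc_w
  dpl <- array(dflat, cache$flat_dim)
  if (!is.null(cache$drop_mask)) dpl <- dpl * cache$drop_mask
  de <- avgpool_backward(dpl, cfg$pool_size, cache$pool_in_len)
  x <- cache$elu_in
  de <- de * ifelse(x > 0, 1, exp(pmin(x, 0)))
  b2 <- bn_backward(de, cache$bn2)
  g$bn2_g <- b2$dgamma; g$bn2_b <- b2$dbeta

  dp <- cfg$depthwise_padding
  bw <- .conv1d_bwd(cache$spw_in, p$spw, b2$dx, 0L, 0L, 1L, TRUE)
  g$spw <- bw$gw; g$spw_b <- bw$gb
  bw <- .conv1d_bwd(cache$sdw_in, p$sdw, bw$gx, dp, dp, cfg$n_maps, FALSE)
  g$sdw <- bw$gw
  bw <- .conv1d_bwd(cache$dw1_in, p$dw1, bw$gx, dp, dp, cfg$n_maps, FALSE)
  g$dw1 <- bw$gw
  dh <- bw$gx

  if (cfg$bn_after_activation) {
    b1 <- bn_backward(dh, cache$bn1)
    dtc <- b1$dx * (cache$relu_in > 0)
  } else {
    dh <- dh * (cache$relu_in > 0)
    b1 <- bn_backward(dh, cache$bn1)
    dtc <- b1$dx
  }
  g$bn1_g <- b1$dgamma; g$bn1_b <- b1$dbeta

  dx <- array(0, dim(cache$x_in))
  off <- 0L
  for (i in seq_along(cfg$temporal_kernels)) {
    k <- cfg$temporal_kernels[i]
    pl <- (k - 1L) %/% 2L
    gi <- dtc[, off + seq_len(cfg$filters_per_kernel), , drop = FALSE]
    bw <- .conv1d_bwd(cache$x_in, p[[paste0("tw", i)]], gi,
                      pl, k - 1L - pl, 1L, TRUE)
    g[[paste0("tw", i)]] <- bw$gw
    g[[paste0("tb", i)]] <- bw$gb
    dx <- dx + bw$gx
    off <- off + cfg$filters_per_kernel
  }

  if (cfg$attention) {
    ab <- attention_backward(p, cache$att, dx)
    g$aw1 <- ab$daw1; g$ab1 <- ab$dab1
    g$aw2 <- ab$daw2; g$ab2 <- ab$dab2
    dx <- ab$dx
  }
  g$.dx <- dx
  g
}

softmax_xent <- function(logits, labels0) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(p)
  idx <- cbind(seq_len(n), labels0 + 1L)
  loss <- -mean(log(pmax(p[idx], .Machine$double.xmin)))
  grad <- p
  grad[idx] <- grad[idx] - 1
  list(loss = loss, grad = grad / n, prob = p)
}
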