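tiny_config <- function(...) {
  micnn_config(n_channels = 3, n_samples = 40, n_classes = 2,
               temporal_kernels = c(3, 4), filters_per_kernel = 2,
               depthwise_kernel = 7, depthwise_padding = 2,
               pool_size = 4, dropout = 0, ...)
}

test_that("stage shapes follow the architecture arithmetic", {
  cfg <- micnn_config(n_channels = 25, n_samples = 1000, n_classes = 4)
  sh <- micnn_shapes(cfg)
  expect_identical(sh$maps[sh$stage == "temporal_concat"], 96L)
  expect_identical(sh$length[sh$stage == "temporal_concat"], 1000L)
  expect_identical(sh$length[sh$stage == "depthwise"], 990L)
  expect_identical(sh$length[sh$stage == "separable"], 980L)
  expect_identical(sh$length[sh$stage == "avg_pool"], 980L %/% 8L)
  expect_identical(sh$length[sh$stage == "dense"], 4L)
  # too-short input names the failing stage
  expect_error(micnn_config(n_channels = 4, n_samples = 16, n_classes = 2),
               "depthwise|separable|avg_pool")
})

test_that("temporal block is length-preserving for every kernel", {
  set.seed(1)
  x <- array(rnorm(2 * 3 * 50), c(2, 3, 50))
  for (k in c(3L, 5L, 9L, 4L)) {  # even kernel: asymmetric padding
    w <- array(rnorm(2 * 3 * k), c(2, 3, k))
    pl <- (k - 1L) %/% 2L
    out <- mieog:::.conv1d_fwd(x, w, numeric(2), pl, k - 1L - pl, 1L)
    expect_identical(dim(out)[3], 50L)
  }
})

test_that("parameter counts reflect the depthwise economy", {
  cfg <- micnn_config(n_channels = 25, n_samples = 1000, n_classes = 4)
  model <- micnn_build(cfg, seed = 1)
  # depthwise stage: one kernel-25 filter per map, no bias
  expect_identical(length(model$params$dw1), 96L * 25L)
  expect_identical(length(model$params$dw1), 2400L)
  # a full convolution of the same shape would carry C times more weights
  full <- 96L * 96L * 25L
  expect_identical(full, 230400L)
  expect_equal(length(model$params$dw1) / full, 1 / 96)
  # doubling filters_per_kernel doubles the temporal-block weights
  cfg2 <- micnn_config(n_channels = 25, n_samples = 1000, n_classes = 4,
                       filters_per_kernel = 64)
  m2 <- micnn_build(cfg2, seed = 1)
  tw <- function(m) sum(sapply(paste0("tw", 1:3), function(n) length(m$params[[n]])))
  expect_identical(tw(m2), 2L * tw(model))
})

test_that("attention parameter count is 2*C*ceiling(C/r) plus biases", {
  for (C in c(12L, 25L)) {
    cfg <- micnn_config(n_channels = C, n_samples = 200, n_classes = 2,
                        filters_per_kernel = 2, pool_size = 8,
                        attention = TRUE, attention_reduction = 4)
    m <- micnn_build(cfg, seed = 1)
    Cr <- as.integer(ceiling(C / 4))
    n_att <- length(m$params$aw1) + length(m$params$aw2) +
      length(m$params$ab1) + length(m$params$ab2)
    expect_identical(n_att, 2L * C * Cr + C + Cr)
  }
})

test_that("backpropagation matches finite differences", {
  cfg <- tiny_config(attention = TRUE, attention_reduction = 2)
  model <- micnn_build(cfg, seed = 2)
  set.seed(3)
  x <- array(rnorm(4 * 3 * 40), c(4, 3, 40))
  y <- c(0L, 1L, 1L, 0L)
  lossfn <- function(m) {
    fw <- mieog:::micnn_forward(m, x, training = TRUE)
    mieog:::softmax_xent(fw$logits, y)$loss
  }
  fw <- mieog:::micnn_forward(model, x, training = TRUE)
  gr <- mieog:::micnn_backward(model, fw$cache,
                               mieog:::softmax_xent(fw$logits, y)$grad)
  eps <- 1e-5
  worst <- 0
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      mp <- model; mp$params[[nm]][i] <- p[i] + eps
      mm <- model; mm$params[[nm]][i] <- p[i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      worst <- max(worst, abs(num - gr[[nm]][i]) /
                     max(1e-4, abs(num) + abs(gr[[nm]][i])))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("logit batch shape matches trials x classes", {
  cfg <- tiny_config()
  model <- micnn_build(cfg, seed = 4)
  x <- array(rnorm(7 * 3 * 40), c(7, 3, 40))
  fw <- mieog:::micnn_forward(model, x)
  expect_identical(dim(fw$logits), c(7L, 2L))
})

test_that("attention gates behave as a sigmoid gating stage", {
  cfg <- tiny_config(attention = TRUE, attention_reduction = 2)
  model <- micnn_build(cfg, seed = 5)
  set.seed(6)
  x <- array(rnorm(5 * 3 * 40), c(5, 3, 40))
  af <- attention_forward(model, x)
  # gates strictly inside (0, 1) for finite input
  expect_true(all(af$gates > 0 & af$gates < 1))
  # zero-initialized gate convolutions: gates exactly 0.5, output = input/2
  m0 <- model
  for (nm in c("aw1", "ab1", "aw2", "ab2")) m0$params[[nm]][] <- 0
  af0 <- attention_forward(m0, x)
  expect_true(all(af0$gates == 0.5))
  expect_equal(af0$gated, x / 2)
  # multiplicative gating: an identically-zero channel stays zero
  x[, 2, ] <- 0
  af2 <- attention_forward(model, x)
  expect_true(all(af2$gated[, 2, ] == 0))
  # gated-output norm scales linearly with the gate (monotone gating)
  expect_equal(sqrt(sum(af$gated[1, 1, ]^2)),
               af$gates[1, 1] * sqrt(sum(x[1, 1, ]^2)), tolerance = 1e-12)
  # plain models refuse attention queries
  expect_error(attention_forward(micnn_build(tiny_config(), seed = 1), x),
               "without the channel-attention")
})

test_that("zeroing one depthwise filter changes only that feature map", {
  cfg <- tiny_config()
  model <- micnn_build(cfg, seed = 7)
  set.seed(8)
  x <- array(rnorm(3 * 3 * 40), c(3, 3, 40))
  h <- array(rnorm(3 * cfg$n_maps * 40), c(3, cfg$n_maps, 40))
  base <- mieog:::.conv1d_fwd(h, model$params$dw1, numeric(0), 2L, 2L,
                              cfg$n_maps)
  pert <- model$params$dw1
  pert[2, 1, ] <- 0
  out <- mieog:::.conv1d_fwd(h, pert, numeric(0), 2L, 2L, cfg$n_maps)
  changed <- sapply(seq_len(cfg$n_maps),
                    function(j) !isTRUE(all.equal(out[, j, ], base[, j, ])))
  expect_identical(which(changed), 2L)
})

test_that("a model with attention disabled equals the plain model", {
  cfg_att <- tiny_config(attention = TRUE, attention_reduction = 2)
  att <- micnn_build(cfg_att, seed = 9)
  plain <- micnn_build(tiny_config(), seed = 9)
  shared <- setdiff(names(att$params), c("aw1", "ab1", "aw2", "ab2"))
  for (nm in shared) plain$params[[nm]] <- att$params[[nm]]
  # neutral gates (0.5) reduce the attention model to the plain model fed x/2
  for (nm in c("aw1", "ab1", "aw2", "ab2")) att$params[[nm]][] <- 0
  set.seed(10)
  x <- array(rnorm(4 * 3 * 40), c(4, 3, 40))
  expect_equal(mieog:::micnn_forward(att, x)$logits,
               mieog:::micnn_forward(plain, x / 2)$logits, tolerance = 1e-12)
})
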