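#' Fit the compact EEG/EOG convolutional classifier
#'
#' Trains the multi-kernel depthwise-separable 1D CNN (optionally with the
#' channel-attention front end) by mini-batch Adam with cross-entropy
#' loss. Unless a held-out `test` set is supplied, the trials are split
#' stratified 80/20 first; channels are z-scored with train-only
#' statistics. After every epoch the held-out accuracy is recorded; the
#' reported `peak_test_accuracy` is the maximum of that trace — note this
#' selects the peak on the test set itself (an optimistic protocol,
#' labelled as such wherever reported).
#'
#' @param dataset an `epoched_dataset`.
#' @param test optional held-out `epoched_dataset`; if supplied, `dataset`
#'   is used entirely for training.
#' @param config optional [micnn_config()]; by default one is built from
#'   the data dimensions and the arguments below.
#' @param attention,filters_per_kernel,temporal_kernels,pool_size,dropout
#'   passed to [micnn_config()] when `config` is NULL.
#' @param epochs training epochs (default 500).
#' @param batch_size mini-batch size (default 64).
#' @param lr Adam learning rate (default 0.001).
#' @param train_fraction,stratified internal split parameters (see
#'   [split_trials()]).
#' @param normalize z-score channels with train statistics (default TRUE)?
#' @param seed integer seed governing split, initialization, shuffling and
#'   dropout; identical seeds give identical accuracy traces. `NULL` uses
#'   the ambient RNG stream.
#' @param verbose print per-epoch progress?
#' @return Object of class `micnn`: the trained `params` and `bn_run`
#'   (final weights), `config`, `trace` (per-epoch held-out accuracy, %),
#'   `peak_test_accuracy` (%), `loss_trace`, `normalization`, `channels`,
#'   `class_names`, `split` (train/test indices when split internally).
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config_planted(seed = 3))
#' fit <- micnn(sim$dataset, filters_per_kernel = 4, epochs = 10,
#'              batch_size = 32, seed = 3)
#' fit$peak_test_accuracy
#' }
#' @export
micnn <- function(dataset, test = NULL, config = NULL,
                  attention = FALSE, filters_per_kernel = 32L,
                  temporal_kernels = c(3L, 5L, 9L), pool_size = 8L,
                  dropout = 0.5, epochs = 500L, batch_size = 64L,
                  lr = 1e-3, train_fraction = 0.8, stratified = TRUE,
                  normalize = TRUE, seed = NULL, verbose = FALSE) {
  with_seed(seed, {
    if (is.null(test)) {
      sp <- split_trials(dataset, train_fraction, stratified)
      train <- sp$train; test <- sp$test
      split <- list(train_index = sp$train_index, test_index = sp$test_index)
    } else {
      train <- dataset
      split <- NULL
    }
    norm <- NULL
    if (normalize) {
      zn <- zscore_normalize(train, test)
      train <- zn$train; test <- zn$test
      norm <- list(center = zn$center, scale = zn$scale)
    }
    if (is.null(config))
      config <- micnn_config(n_channels(train), n_samples(train),
                             n_classes(train),
                             temporal_kernels = temporal_kernels,
                             filters_per_kernel = filters_per_kernel,
                             pool_size = pool_size, dropout = dropout,
                             attention = attention)
    model <- micnn_build(config)
    opt <- adam_state(model$params, lr = lr)
    n <- n_trials(train)
    trace <- numeric(epochs)
    loss_trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- train$data[idx, , , drop = FALSE]
        yb <- train$labels[idx]
        fw <- micnn_forward(model, xb, training = TRUE)
        model$bn_run <- fw$bn_run
        sx <- softmax_xent(fw$logits, yb)
        if (!is.finite(sx$loss))
          stop2("training diverged (loss not finite) at epoch ", ep,
                "; lower the learning rate")
        grads <- micnn_backward(model, fw$cache, sx$grad)
        model$params <- adam_step(opt, model$params, grads)
        ep_loss <- ep_loss + sx$loss; nb <- nb + 1L
      }
      loss_trace[ep] <- ep_loss / nb
      pred <- micnn_predict_labels(model, test$data)
      trace[ep] <- 100 * mean(pred == test$labels)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  test acc %.1f%%",
                        ep, loss_trace[ep], trace[ep]))
    }
    structure(list(config = config, params = model$params,
                   bn_run = model$bn_run,
                   trace = trace, peak_test_accuracy = max(trace),
                   loss_trace = loss_trace, normalization = norm,
                   channels = dataset$channels,
                   class_names = dataset$class_names,
                   split = split, seed = seed),
              class = "micnn")
  })
}

adam_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  e$v <- e$m
  e$t <- 0L
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * gr
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      state$lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + state$eps)
  }
  params
}

micnn_predict_labels <- function(model, x) {
  fw <- micnn_forward(model, x, training = FALSE)
  max.col(fw$logits, ties.method = "first") - 1L
}

#' @export
predict.micnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  check_model_channels(object, newdata)
  x <- newdata$data
  if (!is.null(object$normalization)) {
    for (c in seq_len(dim(x)[2L]))
      x[, c, ] <- (x[, c, ] - object$normalization$center[c]) /
        object$normalization$scale[c]
  }
  fw <- micnn_forward(object, x, training = FALSE)
  if (type == "class") return(max.col(fw$logits, ties.method = "first") - 1L)
  z <- fw$logits - apply(fw$logits, 1L, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- object$class_names
  p
}

#' @export
print.micnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<micnn> %d ch x %d samples -> %d classes | kernels {%s} x %d = %d maps%s\n",
    cfg$n_channels, cfg$n_samples, cfg$n_classes,
    paste(cfg$temporal_kernels, collapse = ","), cfg$filters_per_kernel,
    cfg$n_maps, if (cfg$attention) " | channel attention" else ""))
  cat(sprintf("  %d trainable parameters; %d epochs\n",
              count_parameters(x), length(x$trace)))
  cat(sprintf("  peak test accuracy: %.1f%% (final %.1f%%)\n",
              x$peak_test_accuracy, x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
summary.micnn <- function(object, ...) {
  print(object)
  cat("\nStage shapes:\n")
  print(micnn_shapes(object$config))
  invisible(object)
}

#' @export
plot.micnn <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", xlab = "epoch",
       ylab = "held-out accuracy (%)", ylim = c(0, 100), ...)
  abline(h = x$peak_test_accuracy, lty = 2)
  invisible(x)
}

#' @export
coef.micnn <- function(object, ...) object$params

#' Channel importance from learned attention gates
#'
#' Runs the fitted attention-augmented model's front end over a dataset
#' (applying the model's stored channel normalization) and scores each
#' channel by its gate value averaged over trials. Gates live in (0, 1);
#' channels the trained model amplifies score above 0.5-ish, attenuated
#' ones below.
#'
#' @param model a fitted [micnn()] with `config$attention = TRUE`.
#' @param ds evaluation dataset (normally the held-out test set).
#' @return A `channel_importance` (method `"attention"`); metadata holds
#'   the per-trial gate matrix.
#' @export
attention_importance <- function(model, ds) {
  if (!isTRUE(model$config$attention))
    stop2("model was built without the channel-attention front end")
  check_model_channels(model, ds)
  x <- ds$data
  if (!is.null(model$normalization)) {
    for (c in seq_len(dim(x)[2L]))
      x[, c, ] <- (x[, c, ] - model$normalization$center[c]) /
        model$normalization$scale[c]
  }
  af <- attention_forward(model, x)
  new_importance("attention", colMeans(af$gates), ds$channels,
                 metadata = list(gates = af$gates))
}

#' Trainer handle: compact CNN with an internal split
#'
#' Returns a function `f(dataset) -> accuracy` (peak held-out accuracy,
#' fraction in [0, 1]) wrapping [micnn()] at reduced size, usable as the
#' `trainer` of [random_search()].
#'
#' @param epochs,filters_per_kernel,batch_size,... passed to [micnn()].
#' @return a trainer function.
#' @export
make_micnn_trainer <- function(epochs = 50L, filters_per_kernel = 4L,
                               batch_size = 32L, ...) {
  function(ds) {
    fit <- micnn(ds, epochs = epochs, filters_per_kernel = filters_per_kernel,
                 batch_size = batch_size, ...)
    fit$peak_test_accuracy / 100
  }
}
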