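# Band-power features and a light LDA reference classifier. Used as the
# fast trainer inside random search and as an independent cross-check of
# the network in tests; the network itself is in micnn.R.

#' Log band-power features per trial and channel
#'
#' Power in a frequency band from the trial's FFT periodogram, log
#' transformed — the classical ERD/ERS feature.
#'
#' @param ds an `epoched_dataset`.
#' @param band `c(low, high)` Hz.
#' @return numeric matrix `n_trials x n_channels`.
#' @export
bandpower_features <- function(ds, band = c(8, 12)) {
  fs <- ds$sampling_rate
  L <- n_samples(ds)
  if (band[2L] >= fs / 2 || band[1L] <= 0 || band[1L] >= band[2L])
    stop2("band must satisfy 0 < low < high < Nyquist")
  nf <- floor(L / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * fs / L
  keep <- which(freqs >= band[1L] & freqs <= band[2L])
  if (!length(keep)) stop2("band contains no frequency bins")
  N <- n_trials(ds); C <- n_channels(ds)
  out <- matrix(0, N, C, dimnames = list(NULL, ds$channels$name))
  for (c in seq_len(C)) {
    F <- mvfft(t(matrix(ds$data[, c, ], nrow = N)))[keep, , drop = FALSE]
    out[, c] <- log(colSums(Mod(F)^2) / L + .Machine$double.eps)
  }
  out
}

#' Linear discriminant classifier on log band-power features
#'
#' A deliberately simple reference classifier: per-channel log alpha-band
#' (by default) power, fed to linear discriminant analysis. Fast enough to
#' be trained hundreds of times inside [random_search()].
#'
#' @param train training `epoched_dataset`.
#' @param band frequency band for [bandpower_features()].
#' @return object of class `bandpower_classifier` with a `predict` method
#'   returning 0-based integer labels.
#' @export
bandpower_classifier <- function(train, band = c(8, 12)) {
  feats <- bandpower_features(train, band)
  fit <- suppressWarnings(MASS::lda(feats, grouping = factor(train$labels)))
  structure(list(fit = fit, band = band, channels = train$channels),
            class = "bandpower_classifier")
}

#' @export
predict.bandpower_classifier <- function(object, newdata, ...) {
  check_model_channels(object, newdata)
  feats <- bandpower_features(newdata, object$band)
  as.integer(as.character(predict(object$fit, feats)$class))
}

#' Trainer handle: band-power LDA with an internal split
#'
#' Returns a function `f(dataset) -> accuracy` that splits the dataset
#' (stratified 80/20 by default), fits [bandpower_classifier()] on the
#' training part and returns the held-out accuracy in [0, 1]. Suitable as
#' the `trainer` of [random_search()].
#'
#' @param band frequency band.
#' @param train_fraction split fraction.
#' @param split_seed optional fixed seed for the split (otherwise the
#'   ambient RNG stream, i.e. the seed of the calling search, drives it).
#' @return a trainer function.
#' @export
make_bandpower_trainer <- function(band = c(8, 12), train_fraction = 0.8,
                                   split_seed = NULL) {
  function(ds) {
    sp <- split_trials(ds, train_fraction, stratified = TRUE,
                       seed = split_seed)
    model <- bandpower_classifier(sp$train, band)
    classification_accuracy(model, sp$test)
  }
}
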