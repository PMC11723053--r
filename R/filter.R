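#' Zero-phase FIR band-pass filter
#'
#' Forward-backward (zero-phase) filtering with a Hamming-windowed FIR
#' band-pass, applied independently to every trial and channel. The default
#' 7-35 Hz band brackets the mu and beta rhythms in which motor-imagery
#' activation is expressed, and is applied before common-spatial-pattern
#' fitting. Filter order defaults to `3.3 * fs / low` (rounded to even),
#' the usual window-design rule for a transition width of about the low
#' edge.
#'
#' @param ds an `epoched_dataset`.
#' @param low,high band edges in Hz, `0 < low < high < Nyquist`.
#' @param order FIR order (even); default `round(3.3 * fs / low)`.
#' @return An `epoched_dataset` of identical shape with filtered data.
#' @export
bandpass_filter <- function(ds, low = 7, high = 35, order = NULL) {
  fs <- ds$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop2("band must satisfy 0 < low < high < Nyquist (", fs / 2, " Hz)")
  if (is.null(order)) order <- round(3.3 * fs / low)
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L
  L <- n_samples(ds)
  if (3L * (order + 1L) >= L)
    stop2("epoch too short (", L, " samples) for filter order ", order,
          "; pass a smaller `order`")
  h <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  out <- ds
  N <- n_trials(ds); C <- n_channels(ds)
  for (c in seq_len(C)) {
    X <- matrix(ds$data[, c, ], nrow = N)  # N x L
    out$data[, c, ] <- t(apply(X, 1L, function(x) signal::filtfilt(h, x)))
  }
  out
}

#' Per-channel z-score normalization with train-only statistics
#'
#' Computes each channel's mean and standard deviation over all training
#' trials and samples, and standardizes both sets with those statistics —
#' the input scaling used before network training (importance methods that
#' operate on raw filtered amplitudes skip it).
#'
#' @param train training `epoched_dataset` (statistics source).
#' @param test optional second dataset standardized with the train
#'   statistics.
#' @return list with `train`, `test` (NULL if not supplied), and the
#'   per-channel `center` and `scale` vectors.
#' @export
zscore_normalize <- function(train, test = NULL) {
  C <- n_channels(train)
  center <- numeric(C); scale <- numeric(C)
  for (c in seq_len(C)) {
    v <- train$data[, c, ]
    center[c] <- mean(v)
    scale[c] <- sd(as.vector(v))
  }
  bad <- which(scale < 1e-12 | !is.finite(scale))
  if (length(bad))
    stop2("zero-variance channel(s): ",
          paste(train$channels$name[bad], collapse = ", "))
  names(center) <- names(scale) <- train$channels$name
  apply_norm <- function(ds) {
    for (c in seq_len(C)) ds$data[, c, ] <- (ds$data[, c, ] - center[c]) / scale[c]
    ds
  }
  list(train = apply_norm(train),
       test = if (!is.null(test)) apply_norm(test),
       center = center, scale = scale)
}
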