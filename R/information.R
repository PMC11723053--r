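#' Shannon entropy of a discrete probability vector
#'
#' `-sum(p * log2(p))` in bits, with the convention `0 * log 0 = 0`.
#'
#' @param p non-negative numeric vector summing to 1 (within 1e-9).
#' @return entropy in bits.
#' @examples
#' shannon_entropy(rep(0.25, 4))   # 2 bits
#' shannon_entropy(c(0.5, 0.25, 0.25))  # 1.5 bits
#' @export
shannon_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0))
    stop2("probabilities must be finite and non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop2("probabilities must sum to 1 (got ", format(sum(p)), ")")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Equal-width bin indices over a variable's own range. A constant vector
# occupies a single bin (handled by callers with a warning).
bin_indices <- function(x, n_bins) {
  r <- range(x)
  if (r[1L] == r[2L]) return(rep(1L, length(x)))
  idx <- floor((x - r[1L]) / (r[2L] - r[1L]) * n_bins) + 1L
  idx[idx > n_bins] <- n_bins
  idx
}

#' Histogram mutual information between two sample vectors
#'
#' Plug-in estimate `I(X;Y) = H(X) + H(Y) - H(X,Y)` on equal-width-binned
#' marginal and joint histograms, each variable binned over its own range.
#' Returned in bits; non-negative by construction.
#'
#' @param x,y numeric vectors of equal length (>= `n_bins` recommended).
#' @param n_bins number of equal-width bins per variable (default 64).
#' @return mutual information in bits.
#' @examples
#' set.seed(1)
#' x <- rnorm(1e4)
#' mutual_information(x, x)          # = H(binned x)
#' mutual_information(x, rnorm(1e4)) # near 0
#' @export
mutual_information <- function(x, y, n_bins = 64L) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  if (!is_count(n_bins, 2L)) stop2("n_bins must be an integer >= 2")
  n_bins <- as.integer(n_bins)
  bx <- bin_indices(x, n_bins)
  by <- bin_indices(y, n_bins)
  if (max(bx) == min(bx) || max(by) == min(by)) {
    warning("constant input occupies a single bin; mutual information is 0")
    return(0)
  }
  n <- length(x)
  joint <- tabulate((bx - 1L) * n_bins + by, nbins = n_bins * n_bins) / n
  hx <- shannon_entropy(tabulate(bx, n_bins) / n)
  hy <- shannon_entropy(tabulate(by, n_bins) / n)
  hxy <- shannon_entropy(joint / sum(joint))
  max(hx + hy - hxy, 0)
}

#' Mutual information between every EOG and EEG channel pair
#'
#' For each (EOG, EEG) channel pair, the samples are the concatenation of
#' all trials' time series; the pairwise histogram mutual information
#' quantifies how much signal the two electrodes share. High values for an
#' EOG-EEG pair indicate that the ocular channel carries signal overlapping
#' the neural channel (leakage in either direction).
#'
#' @param ds an `epoched_dataset` containing at least one EOG and one EEG
#'   channel.
#' @param n_bins histogram bins per variable (default 64).
#' @return Object of class `mi_result`: `matrix` (`n_eog x n_eeg`, bits,
#'   dimnames = channel names), `marginal_entropies` (bits, all channels),
#'   `n_bins`.
#' @export
mi_matrix <- function(ds, n_bins = 64L) {
  eog <- which(ds$channels$modality == "EOG")
  eeg <- which(ds$channels$modality == "EEG")
  if (!length(eog)) stop2("dataset has no EOG channels")
  if (!length(eeg)) stop2("dataset has no EEG channels")
  n_bins <- as.integer(n_bins)
  flat <- lapply(seq_len(n_channels(ds)), function(c) as.vector(ds$data[, c, ]))
  n <- length(flat[[1L]])
  bins <- lapply(flat, bin_indices, n_bins = n_bins)
  H <- vapply(bins, function(b) shannon_entropy(tabulate(b, n_bins) / n),
              numeric(1))
  names(H) <- ds$channels$name
  M <- matrix(0, length(eog), length(eeg),
              dimnames = list(ds$channels$name[eog], ds$channels$name[eeg]))
  for (i in seq_along(eog)) {
    bi <- bins[[eog[i]]]
    for (j in seq_along(eeg)) {
      bj <- bins[[eeg[j]]]
      joint <- tabulate((bi - 1L) * n_bins + bj, nbins = n_bins * n_bins) / n
      M[i, j] <- max(H[eog[i]] + H[eeg[j]] - shannon_entropy(joint), 0)
    }
  }
  structure(list(matrix = M, marginal_entropies = H, n_bins = n_bins),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result> %d EOG x %d EEG channel pairs, %d bins\n",
              nrow(x$matrix), ncol(x$matrix), x$n_bins))
  for (i in seq_len(nrow(x$matrix))) {
    top <- sort(x$matrix[i, ], decreasing = TRUE)[seq_len(min(3L, ncol(x$matrix)))]
    cat(sprintf("  %s: top partners %s\n", rownames(x$matrix)[i],
                paste(sprintf("%s (%.3f b)", names(top), top), collapse = ", ")))
  }
  invisible(x)
}
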