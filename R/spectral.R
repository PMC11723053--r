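# Multitaper spectral estimation.
#
# Discrete prolate spheroidal (Slepian) tapers are obtained from the
# classical symmetric tridiagonal eigenproblem: for sequence length N and
# half-bandwidth W = NW/N, the tridiagonal matrix with diagonal
# ((N-1-2t)/2)^2 cos(2*pi*W) and off-diagonal t(N-t)/2 has the dpss as its
# leading eigenvectors. Tapers are cached per (N, NW).
dpss_tapers <- function(N, NW = 4, K = 2 * NW - 1) {
  key <- paste0("dpss_", N, "_", NW, "_", K)
  cached <- .mieog_env[[key]]
  if (!is.null(cached)) return(cached)
  W <- NW / N
  t <- seq_len(N) - 1L
  dg <- ((N - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  tt <- seq_len(N - 1)
  od <- tt * (N - tt) / 2
  A <- matrix(0, N, N)
  diag(A) <- dg
  A[cbind(1:(N - 1), 2:N)] <- od
  A[cbind(2:N, 1:(N - 1))] <- od
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors[, seq_len(K), drop = FALSE]
  # polarity convention: each taper starts non-negative (symmetric ones
  # positive at the centre); sign does not affect power
  for (k in seq_len(K)) {
    s <- sum(V[, k])
    if ((k %% 2L == 1L && s < 0) || (k %% 2L == 0L && V[2L, k] - V[1L, k] < 0))
      V[, k] <- -V[, k]
  }
  .mieog_env[[key]] <- V
  V
}

#' Multitaper power spectral density of an epoched dataset
#'
#' Trial-averaged multitaper PSD per channel, in uV^2/Hz, over a requested
#' frequency range (0.1-40 Hz by default, the range in which both the 1/f
#' background and the mu/beta motor-imagery bands live). Tapers are discrete
#' prolate spheroidal sequences with time-bandwidth product `bandwidth`
#' (default 4, giving `2*bandwidth - 1 = 7` tapers). With
#' `per_class = TRUE` a separate estimate is returned per class.
#'
#' @param ds an `epoched_dataset`.
#' @param fmin,fmax frequency range in Hz; `fmax` must be below Nyquist.
#' @param bandwidth time-bandwidth product NW (>= 1).
#' @param per_class average within class instead of over all trials?
#' @return An object of class `spectral_estimate` with fields
#'   `frequencies` (Hz, strictly increasing), `power`
#'   (`n_channels x n_freqs`, linear scale), `in_decibels = FALSE`,
#'   `channels`; or a named list of such objects when `per_class = TRUE`.
#'   Convert to decibels with `10*log10(power)`.
#' @export
multitaper_psd <- function(ds, fmin = 0.1, fmax = 40, bandwidth = 4,
                           per_class = FALSE) {
  fs <- ds$sampling_rate
  if (fmax >= fs / 2) stop2("fmax must be below the Nyquist frequency (",
                            fs / 2, " Hz)")
  if (fmin >= fmax) stop2("fmin must be below fmax")
  L <- n_samples(ds)
  V <- dpss_tapers(L, NW = bandwidth)
  K <- ncol(V)
  nf <- floor(L / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * fs / L
  keep <- which(freqs >= fmin & freqs <= fmax)

  psd_of <- function(trials) {
    acc <- matrix(0, n_channels(ds), nf)
    for (c in seq_len(n_channels(ds))) {
      X <- t(ds$data[trials, c, , drop = FALSE][, 1L, ])  # L x n_trials
      if (length(trials) == 1L) X <- matrix(ds$data[trials, c, ], ncol = 1L)
      P <- matrix(0, nf, ncol(X))
      for (k in seq_len(K)) {
        F <- mvfft(X * V[, k])[seq_len(nf), , drop = FALSE]
        P <- P + (Mod(F)^2) / fs
      }
      P <- P / K
      # one-sided: double interior bins (not DC, not Nyquist when L even)
      dbl <- rep(2, nf); dbl[1L] <- 1
      if (L %% 2L == 0L) dbl[nf] <- 1
      acc[c, ] <- rowMeans(P) * dbl
    }
    structure(list(frequencies = freqs[keep],
                   power = acc[, keep, drop = FALSE],
                   in_decibels = FALSE,
                   channels = ds$channels),
              class = "spectral_estimate")
  }

  if (!per_class) return(psd_of(seq_len(n_trials(ds))))
  out <- lapply(seq_along(ds$class_names) - 1L,
                function(k) psd_of(which(ds$labels == k)))
  names(out) <- ds$class_names
  out
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d channels x %d frequencies (%.3g-%.3g Hz)%s\n",
              nrow(x$power), length(x$frequencies),
              min(x$frequencies), max(x$frequencies),
              if (x$in_decibels) " [dB]" else " [uV^2/Hz]"))
  invisible(x)
}

#' @export
plot.spectral_estimate <- function(x, db = TRUE, ...) {
  p <- if (db) 10 * log10(pmax(x$power, .Machine$double.xmin)) else x$power
  plot(NA, xlim = range(x$frequencies), ylim = range(p),
       xlab = "frequency (Hz)",
       ylab = if (db) "PSD (dB re uV^2/Hz)" else "PSD (uV^2/Hz)", ...)
  for (c in seq_len(nrow(p)))
    lines(x$frequencies, p[c, ],
          col = if (x$channels$modality[c] == "EOG") "red" else gray(0.3))
  invisible(x)
}

#' Export a spectral estimate as long-format CSV
#'
#' Columns: `frequency`, `channel`, `modality`, `power_db`.
#'
#' @param est a `spectral_estimate`.
#' @param path output CSV path.
#' @return invisibly, the exported data frame.
#' @export
write_psd_csv <- function(est, path) {
  df <- data.frame(
    frequency = rep(est$frequencies, each = nrow(est$power)),
    channel = rep(est$channels$name, length(est$frequencies)),
    modality = rep(est$channels$modality, length(est$frequencies)),
    power_db = as.vector(10 * log10(pmax(est$power, .Machine$double.xmin))))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
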