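# Shared fixture builders (all generated in code at test time).

# Small white-noise dataset with named channels and balanced labels.
toy_dataset <- function(n_trials = 16, channels = c("C3", "Cz", "C4", "EOG0"),
                        modality = NULL, n_samples = 64, n_classes = 2,
                        sampling_rate = 128, seed = 1) {
  if (is.null(modality))
    modality <- ifelse(grepl("^EOG", channels), "EOG", "EEG")
  set.seed(seed)
  x <- array(rnorm(n_trials * length(channels) * n_samples),
             c(n_trials, length(channels), n_samples))
  epoched_dataset(x, rep(seq_len(n_classes) - 1L, length.out = n_trials),
                  channels, modality, sampling_rate)
}

# Dataset holding pure sinusoids on every channel.
sinusoid_dataset <- function(freq, amplitude = 1, n_trials = 4, n_channels = 2,
                             n_samples = 256, sampling_rate = 128) {
  t <- (seq_len(n_samples) - 1) / sampling_rate
  x <- array(0, c(n_trials, n_channels, n_samples))
  for (tr in seq_len(n_trials)) for (c in seq_len(n_channels))
    x[tr, c, ] <- amplitude * sin(2 * pi * freq * t + (tr + c) * 0.7)
  epoched_dataset(x, rep(0:1, length.out = n_trials),
                  paste0("ch", seq_len(n_channels)), "EEG", sampling_rate)
}

# Two-channel dataset whose per-class trace-normalized covariances are
# exactly diag(4,1)/5 and diag(1,4)/5: every class-a trial has channel
# rows (2,0)/(0,1) patterns, class-b the transpose arrangement.
csp_toy_dataset <- function(n_per_class = 4) {
  xa <- rbind(c(2, 0), c(0, 1))   # X %*% t(X) = diag(4, 1)
  xb <- rbind(c(1, 0), c(0, 2))   # diag(1, 4)
  n <- 2 * n_per_class
  x <- array(0, c(n, 2, 2))
  for (i in seq_len(n_per_class)) {
    x[i, , ] <- xa
    x[n_per_class + i, , ] <- xb
  }
  epoched_dataset(x, rep(0:1, each = n_per_class), c("chA", "chB"),
                  "EEG", 100)
}

# Dense-grid maximizer of the Rayleigh quotient w'Sw / w'Rw over unit
# vectors: the independent oracle for CSP eigenvalues (2-3 channels).
rayleigh_grid_max <- function(S, R, n_grid = 400) {
  C <- nrow(S)
  best <- -Inf
  if (C == 2) {
    for (a in seq(0, pi, length.out = n_grid)) {
      w <- c(cos(a), sin(a))
      best <- max(best, (w %*% S %*% w) / (w %*% R %*% w))
    }
  } else if (C == 3) {
    for (a in seq(0, pi, length.out = n_grid)) {
      for (b in seq(0, 2 * pi, length.out = n_grid)) {
        w <- c(sin(a) * cos(b), sin(a) * sin(b), cos(a))
        best <- max(best, (w %*% S %*% w) / (w %*% R %*% w))
      }
    }
  } else stop("oracle supports 2-3 channels only")
  as.numeric(best)
}

# Plug-in mutual information by direct summation over an exact joint
# probability table (brute-force oracle).
mi_bruteforce <- function(joint) {
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    p <- joint[i, j]
    if (p > 0) s <- s + p * log2(p / (px[i] * py[j]))
  }
  s
}
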