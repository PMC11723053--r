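#' Common spatial patterns by generalized eigendecomposition
#'
#' Fits CSP between two classes (or one class against the rest): with
#' `S` and `R` the trial-averaged, trace-normalized covariance matrices of
#' class a and class b, the spatial filters `w` maximize the variance ratio
#' `w' S w / w' R w` and solve the generalized eigenproblem `S w = lambda R w`.
#' Filters are returned in descending eigenvalue order; the spatial
#' patterns — how each extracted source projects back onto the electrodes,
#' the quantity inspected for channel importance — are the inverse
#' transpose of the filter matrix.
#'
#' A small shrinkage `reg * I` (on the trace-normalized covariances,
#' default 1e-6) keeps the problem well posed when covariances are near
#' singular.
#'
#' @param ds an `epoched_dataset`, normally band-pass filtered to 7-35 Hz
#'   first (see [bandpass_filter()]).
#' @param class_a integer class label (0-based) whose variance is
#'   maximized.
#' @param class_b second class label, or `NULL` for one-vs-rest (all other
#'   classes pooled).
#' @param reg shrinkage regularization added as `reg * I`.
#' @return Object of class `csp_fit`: `filters_w` (C x C, columns are
#'   filters), `eigenvalues_lambda` (descending), `patterns` (C x C,
#'   `t(solve(filters_w))`), `class_pair`, `channels`.
#' @export
csp_fit <- function(ds, class_a, class_b = NULL, reg = 1e-6) {
  labs <- ds$labels
  if (!class_a %in% labs) stop2("class_a (", class_a, ") has no trials")
  if (!is.null(class_b) && !class_b %in% labs)
    stop2("class_b (", class_b, ") has no trials")
  idx_a <- which(labs == class_a)
  idx_b <- if (is.null(class_b)) which(labs != class_a) else which(labs == class_b)

  S <- class_cov(ds, idx_a)
  R <- class_cov(ds, idx_b)
  C <- n_channels(ds)
  if (reg > 0) {
    S <- S + reg * diag(C)
    R <- R + reg * diag(C)
  }
  eR <- eigen(R, symmetric = TRUE)
  if (min(eR$values) < 1e-12 * max(eR$values))
    stop2("class covariance is singular; increase `reg` (shrinkage)")
  P <- diag(1 / sqrt(eR$values)) %*% t(eR$vectors)  # whitener of R
  eT <- eigen(P %*% S %*% t(P), symmetric = TRUE)
  W <- t(P) %*% eT$vectors  # columns: filters, eigenvalues descending
  lam <- eT$values
  colnames(W) <- paste0("CSP", seq_len(C) - 1L)
  patterns <- t(solve(W))
  colnames(patterns) <- colnames(W)
  rownames(W) <- rownames(patterns) <- ds$channels$name
  structure(list(filters_w = W, eigenvalues_lambda = lam,
                 patterns = patterns,
                 class_pair = if (is.null(class_b))
                   paste0("one-vs-rest: ", ds$class_names[class_a + 1L])
                 else paste(ds$class_names[c(class_a, class_b) + 1L],
                            collapse = " vs "),
                 channels = ds$channels),
            class = "csp_fit")
}

# Trial-averaged, trace-normalized covariance over a set of trials.
class_cov <- function(ds, idx) {
  C <- n_channels(ds)
  acc <- matrix(0, C, C)
  for (t in idx) {
    X <- matrix(ds$data[t, , ], nrow = C)
    S <- X %*% t(X)
    tr <- sum(diag(S))
    if (tr > 0) acc <- acc + S / tr
  }
  acc / length(idx)
}

#' @export
print.csp_fit <- function(x, ...) {
  cat(sprintf("<csp_fit> %s; %d filters, lambda in [%.3g, %.3g]\n",
              x$class_pair, ncol(x$filters_w),
              min(x$eigenvalues_lambda), max(x$eigenvalues_lambda)))
  invisible(x)
}

#' Channel importance from CSP pattern activations
#'
#' Per-channel activation is the absolute spatial-pattern coefficient for
#' each of the first `n_patterns` patterns (descending eigenvalue order,
#' the most informative end); the summary score per channel is the maximum
#' activation over those patterns.
#'
#' @param fit a [csp_fit()].
#' @param n_patterns number of leading patterns inspected (default 5).
#' @return A `channel_importance` object (method `"csp_pattern"`); its
#'   metadata holds the `n_patterns x C` activation matrix.
#' @export
csp_pattern_activation <- function(fit, n_patterns = 5L) {
  C <- ncol(fit$patterns)
  if (n_patterns > C) stop2("n_patterns exceeds channel count")
  act <- t(abs(fit$patterns[, seq_len(n_patterns), drop = FALSE]))
  rownames(act) <- paste0("CSP", seq_len(n_patterns) - 1L)
  new_importance("csp_pattern", apply(act, 2L, max), fit$channels,
                 metadata = list(activations = act,
                                 class_pair = fit$class_pair,
                                 eigenvalues = fit$eigenvalues_lambda[seq_len(n_patterns)]))
}

#' CSP channel importance for a (possibly multi-class) dataset
#'
#' Experiment driver: band-pass filters to the motor-imagery range, fits
#' CSP (two-class directly; more classes one-vs-rest per class), pools all
#' spatial patterns and re-ranks them by eigenvalue contrast `|lambda - 1|`,
#' then scores every channel by its maximum absolute pattern coefficient
#' over the `n_patterns` most contrasting patterns.
#'
#' @param ds an `epoched_dataset` (unfiltered; filtering applied here).
#' @param n_patterns number of pooled patterns inspected (default 5).
#' @param band band-pass edges in Hz before fitting (default `c(7, 35)`).
#' @param reg shrinkage passed to [csp_fit()].
#' @return A `channel_importance` object (method `"csp_pattern"`).
#' @export
csp_importance <- function(ds, n_patterns = 5L, band = c(7, 35), reg = 1e-6) {
  dsf <- bandpass_filter(ds, band[1L], band[2L])
  K <- n_classes(dsf)
  if (K == 2L) {
    fit <- csp_fit(dsf, 0L, 1L, reg = reg)
    pats <- fit$patterns
    lam <- fit$eigenvalues_lambda
  } else {
    fits <- lapply(seq_len(K) - 1L, function(k) csp_fit(dsf, k, NULL, reg = reg))
    pats <- do.call(cbind, lapply(fits, `[[`, "patterns"))
    lam <- unlist(lapply(fits, `[[`, "eigenvalues_lambda"))
  }
  ord <- order(-abs(lam - 1), seq_along(lam))
  take <- ord[seq_len(min(n_patterns, length(ord)))]
  act <- t(abs(pats[, take, drop = FALSE]))
  new_importance("csp_pattern", apply(act, 2L, max), ds$channels,
                 metadata = list(activations = act, eigenvalues = lam[take],
                                 band = band, n_classes = K))
}
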