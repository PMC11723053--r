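#' Channel-importance result
#'
#' Common return type of all channel-importance methods: a per-channel
#' score vector and the ranking obtained by sorting scores in descending
#' order, ties broken by ascending channel index (deterministic reports).
#' Channels with undefined scores (e.g. never drawn by random search) carry
#' `NA` and rank last.
#'
#' @param method method label.
#' @param scores numeric per-channel scores (NA allowed).
#' @param channels channel metadata data frame (`name`, `modality`,
#'   `index`).
#' @param metadata list of method parameters / extras.
#' @return object of class `channel_importance` with fields `method`,
#'   `scores` (named), `ranking` (integer, 1-based positions by
#'   descending score), `channels`, `metadata`.
#' @export
new_importance <- function(method, scores, channels, metadata = list()) {
  scores <- as.numeric(scores)
  names(scores) <- channels$name
  ranking <- order(-scores, seq_along(scores), na.last = TRUE)
  structure(list(method = method, scores = scores, ranking = ranking,
                 channels = channels, metadata = metadata),
            class = "channel_importance")
}

#' @export
print.channel_importance <- function(x, n = 10L, ...) {
  cat(sprintf("<channel_importance> method = %s\n", x$method))
  top <- x$ranking[seq_len(min(n, length(x$ranking)))]
  df <- data.frame(rank = seq_along(top),
                   channel = x$channels$name[top],
                   modality = x$channels$modality[top],
                   score = x$scores[top], row.names = NULL)
  print(df, digits = 4)
  if (anyNA(x$scores))
    cat("  (channels with NA score were never evaluated)\n")
  invisible(x)
}

#' Top-ranked channel names of an importance result
#'
#' @param x a `channel_importance`.
#' @param n how many channels.
#' @return character vector of channel names, best first.
#' @export
top_channels <- function(x, n = 5L) {
  x$channels$name[x$ranking[seq_len(min(n, length(x$ranking)))]]
}

#' Export importance scores as CSV
#'
#' Columns: `channel`, `modality`, `score`, `rank`.
#'
#' @param x a `channel_importance`.
#' @param path output CSV path.
#' @return invisibly, the exported data frame.
#' @export
write_importance_csv <- function(x, path) {
  rank <- integer(length(x$scores))
  rank[x$ranking] <- seq_along(x$ranking)
  df <- data.frame(channel = x$channels$name, modality = x$channels$modality,
                   score = unname(x$scores), rank = rank)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

# Fraction of trials classified correctly by `model` on `ds` (via the
# model's predict method, which must return 0-based integer labels).
classification_accuracy <- function(model, ds) {
  mean(predict(model, ds) == ds$labels)
}

#' Permutation importance of each channel for a trained classifier
#'
#' For each channel, its trials are permuted across the trial axis
#' (waveforms intact, trial-label assignment broken) and the model is
#' re-evaluated; the importance score is the baseline accuracy minus the
#' mean permuted accuracy over `n_repeats` draws. Channels the model does
#' not rely on score near zero.
#'
#' @param model a fitted classifier with a `predict(model, dataset)` method
#'   returning 0-based integer labels (e.g. [micnn()] or
#'   [bandpower_classifier()]).
#' @param ds evaluation dataset (normally the held-out test set); its
#'   channel count must match the model's.
#' @param n_repeats permutations per channel (default 10).
#' @param seed integer seed; deterministic given it.
#' @return A `channel_importance` (method `"permutation"`); metadata holds
#'   the baseline accuracy and per-repeat accuracies.
#' @export
permutation_importance <- function(model, ds, n_repeats = 10L, seed = NULL) {
  check_model_channels(model, ds)
  if (!is_count(n_repeats)) stop2("n_repeats must be >= 1")
  base <- classification_accuracy(model, ds)
  C <- n_channels(ds)
  N <- n_trials(ds)
  acc <- matrix(0, C, n_repeats)
  with_seed(seed, {
    for (c in seq_len(C)) {
      for (r in seq_len(n_repeats)) {
        perm <- sample.int(N)
        ds2 <- ds
        ds2$data[, c, ] <- ds$data[perm, c, ]
        acc[c, r] <- classification_accuracy(model, ds2)
      }
    }
  })
  new_importance("permutation", base - rowMeans(acc), ds$channels,
                 metadata = list(baseline_accuracy = base,
                                 permuted_accuracy = acc,
                                 n_repeats = n_repeats))
}

check_model_channels <- function(model, ds) {
  mc <- model_channel_names(model)
  if (is.null(mc)) return(invisible(TRUE))
  if (length(mc) != n_channels(ds))
    stop2("model expects ", length(mc), " channels but dataset has ",
          n_channels(ds))
  invisible(TRUE)
}

model_channel_names <- function(model) {
  if (!is.null(model$channels)) model$channels$name else NULL
}

#' Occurrence-mean channel scores from evaluated subsets
#'
#' Given a list of channel subsets and the accuracy achieved by a model
#' trained on each, every channel's score is the mean accuracy over the
#' subsets containing it (the accuracy of a subset is shared as a weight by
#' all its members). Channels occurring in no subset get `NA`.
#'
#' @param subsets list of integer vectors (1-based channel positions).
#' @param weights numeric vector, one accuracy per subset.
#' @param n_channels total channel count.
#' @return numeric vector of length `n_channels` (NA where unseen).
#' @examples
#' channel_subset_scores(list(c(1, 2), c(2, 3), c(1, 3)),
#'                       c(0.6, 0.8, 0.7), 3)  # 0.65 0.70 0.75
#' @export
channel_subset_scores <- function(subsets, weights, n_channels) {
  if (length(subsets) != length(weights))
    stop2("one weight per subset required")
  tot <- numeric(n_channels)
  cnt <- integer(n_channels)
  for (j in seq_along(subsets)) {
    s <- subsets[[j]]
    tot[s] <- tot[s] + weights[j]
    cnt[s] <- cnt[s] + 1L
  }
  out <- ifelse(cnt > 0L, tot / pmax(cnt, 1L), NA_real_)
  out
}

#' Random-search channel importance
#'
#' Wrapper-based selection by uniform random subsets: each iteration draws
#' `subset_size` distinct channels with equal probability, trains and
#' evaluates a classifier on that montage via `trainer`, and assigns the
#' resulting accuracy as the subset's weight; each channel's score is the
#' mean weight over the subsets containing it
#' (see [channel_subset_scores()]).
#'
#' @param ds an `epoched_dataset`.
#' @param subset_size channels per subset (default 6).
#' @param n_iterations number of random subsets (default 500).
#' @param trainer function taking the channel-subset dataset and returning
#'   a test accuracy in [0, 1]; see [make_bandpower_trainer()] and
#'   [make_micnn_trainer()].
#' @param seed integer seed; subset draws and trainer randomness are
#'   deterministic given it.
#' @return A `channel_importance` (method `"random_search"`); channels
#'   never drawn score `NA` (with a warning), and metadata records the
#'   subsets and weights.
#' @export
random_search <- function(ds, subset_size = 6L, n_iterations = 500L,
                          trainer = make_bandpower_trainer(), seed = NULL) {
  C <- n_channels(ds)
  if (subset_size > C) stop2("subset_size exceeds channel count")
  if (!is_count(n_iterations)) stop2("n_iterations must be >= 1")
  subsets <- vector("list", n_iterations)
  weights <- numeric(n_iterations)
  with_seed(seed, {
    for (j in seq_len(n_iterations)) {
      s <- sort(sample.int(C, subset_size))
      subsets[[j]] <- s
      weights[j] <- trainer(select_channels(ds, ds$channels$name[s]))
    }
  })
  scores <- channel_subset_scores(subsets, weights, C)
  if (anyNA(scores))
    warning(sum(is.na(scores)), " channel(s) were never selected; ",
            "their scores are NA (increase n_iterations)")
  new_importance("random_search", scores, ds$channels,
                 metadata = list(subset_size = subset_size,
                                 n_iterations = n_iterations,
                                 subsets = subsets, weights = weights))
}
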