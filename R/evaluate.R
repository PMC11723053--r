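#' Evaluate montage configurations by repeated random splits
#'
#' The subject-wise evaluation protocol: for each named channel set (e.g.
#' all-EEG, EOG-only, reduced EEG + EOG), the dataset is restricted to
#' those channels and the network is trained on `n_splits` independent
#' stratified 80/20 splits; the row reported per configuration is the mean
#' of the per-split peak held-out accuracies. Split seeds derive
#' deterministically from the master seed as `seed + split_index`.
#'
#' @param dataset an `epoched_dataset`.
#' @param channel_sets named list of channel-name vectors.
#' @param n_splits independent random splits per configuration (default 5).
#' @param seed master integer seed.
#' @param ... training arguments passed to [micnn()] (e.g. `epochs`,
#'   `filters_per_kernel`, `attention`).
#' @return An [accuracy_table()] with one row per configuration; attribute
#'   `"per_split"` holds the full peak-accuracy matrix.
#' @export
evaluate_configurations <- function(dataset, channel_sets, n_splits = 5L,
                                    seed = 1L, ...) {
  if (is.null(names(channel_sets)) || any(!nzchar(names(channel_sets))))
    stop2("`channel_sets` must be a named list")
  peaks <- matrix(0, length(channel_sets), n_splits,
                  dimnames = list(names(channel_sets), NULL))
  for (i in seq_along(channel_sets)) {
    ds_sub <- select_channels(dataset, channel_sets[[i]])
    for (s in seq_len(n_splits)) {
      fit <- micnn(ds_sub, seed = seed + s, ...)
      peaks[i, s] <- fit$peak_test_accuracy
    }
  }
  tab <- accuracy_table(subject = rep(dataset$subject_id %||% "pooled",
                                      length(channel_sets)),
                        configuration = names(channel_sets),
                        accuracy = rowMeans(peaks))
  attr(tab, "per_split") <- peaks
  tab
}
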