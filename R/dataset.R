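#' Epoched multi-channel EEG/EOG dataset
#'
#' The common container passed between all tools in the package: a numeric
#' array of `n_trials x n_channels x n_samples` amplitudes (microvolts),
#' integer class labels coded `0..n_classes-1`, per-channel metadata with an
#' EEG/EOG modality tag, and the sampling rate in Hz.
#'
#' @param data numeric 3-d array, `trials x channels x samples`.
#' @param labels integer vector of length `n_trials`, values in
#'   `0..n_classes-1`; every class must occur at least once.
#' @param channel_names character vector naming the channels (unique).
#' @param modality character vector, `"EEG"` or `"EOG"` per channel.
#' @param sampling_rate sampling frequency in Hz (positive).
#' @param class_names optional character vector naming the classes.
#' @param subject_id optional subject identifier.
#' @return An object of class `epoched_dataset`: a list with elements
#'   `data`, `labels`, `class_names`, `channels` (data frame with columns
#'   `name`, `modality` and 0-based `index`), `sampling_rate`, `subject_id`.
#' @examples
#' x <- array(rnorm(20 * 3 * 50), c(20, 3, 50))
#' ds <- epoched_dataset(x, rep(0:1, 10), c("C3", "Cz", "EOG0"),
#'                       c("EEG", "EEG", "EOG"), 250)
#' ds
#' @export
epoched_dataset <- function(data, labels, channel_names, modality,
                            sampling_rate, class_names = NULL,
                            subject_id = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop2("`data` must be a 3-d array (trials x channels x samples)")
  labels <- as.integer(labels)
  n_classes <- max(labels) + 1L
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes) - 1L)
  modality <- match.arg(modality, c("EEG", "EOG"), several.ok = TRUE)
  if (length(modality) == 1L) modality <- rep(modality, length(channel_names))
  channels <- data.frame(
    name = as.character(channel_names),
    modality = modality,
    index = seq_along(channel_names) - 1L,
    stringsAsFactors = FALSE
  )
  ds <- structure(
    list(data = data, labels = labels, class_names = as.character(class_names),
         channels = channels, sampling_rate = as.numeric(sampling_rate),
         subject_id = subject_id),
    class = "epoched_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate an epoched dataset's internal consistency
#'
#' Checks the container invariants (dimension agreement, label coverage,
#' unique channel names, positive sampling rate) and reports every violation
#' found in a single error.
#'
#' @param ds an `epoched_dataset`.
#' @return `ds`, invisibly, if valid.
#' @export
validate_dataset <- function(ds) {
  problems <- character()
  d <- dim(ds$data)
  if (length(ds$labels) != d[1L])
    problems <- c(problems, sprintf(
      "labels length (%d) != number of trials (%d)", length(ds$labels), d[1L]))
  if (nrow(ds$channels) != d[2L])
    problems <- c(problems, sprintf(
      "channel metadata rows (%d) != number of channels (%d)",
      nrow(ds$channels), d[2L]))
  if (anyDuplicated(ds$channels$name))
    problems <- c(problems, "channel names are not unique")
  if (!identical(ds$channels$index, seq_len(nrow(ds$channels)) - 1L))
    problems <- c(problems, "channel indices are not 0..C-1")
  k <- length(ds$class_names)
  if (any(ds$labels < 0L | ds$labels >= k))
    problems <- c(problems, sprintf("labels outside 0..%d", k - 1L))
  if (!all((seq_len(k) - 1L) %in% ds$labels))
    problems <- c(problems, "some class in 0..n_classes-1 has no trials")
  if (!is.finite(ds$sampling_rate) || ds$sampling_rate <= 0)
    problems <- c(problems, "sampling_rate must be positive")
  if (d[3L] < 1L) problems <- c(problems, "n_samples must be >= 1")
  if (length(problems))
    stop2("invalid epoched_dataset:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(ds)
}

n_trials <- function(ds) dim(ds$data)[1L]
n_channels <- function(ds) dim(ds$data)[2L]
n_samples <- function(ds) dim(ds$data)[3L]
n_classes <- function(ds) length(ds$class_names)

#' Names of the EOG (or EEG) channels of a dataset
#'
#' @param ds an `epoched_dataset`.
#' @param modality `"EOG"` or `"EEG"`.
#' @return character vector of channel names.
#' @export
channels_of <- function(ds, modality = c("EOG", "EEG")) {
  modality <- match.arg(modality)
  ds$channels$name[ds$channels$modality == modality]
}

#' @export
print.epoched_dataset <- function(x, ...) {
  d <- dim(x$data)
  eog <- sum(x$channels$modality == "EOG")
  cat(sprintf(
    "<epoched_dataset> %d trials x %d channels (%d EEG + %d EOG) x %d samples @ %g Hz\n",
    d[1L], d[2L], d[2L] - eog, eog, d[3L], x$sampling_rate))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L))
  cat(sprintf("  trials/class: %s\n", paste(as.integer(tab), collapse = ", ")))
  if (!is.null(x$subject_id)) cat(sprintf("  subject: %s\n", x$subject_id))
  invisible(x)
}

#' @export
summary.epoched_dataset <- function(object, ...) {
  print(object)
  cat(sprintf("  amplitude range: [%.3g, %.3g] uV\n",
              min(object$data), max(object$data)))
  invisible(object)
}

#' Select channels by name
#'
#' Returns a dataset restricted to the named channels, in the given order,
#' with channel indices re-assigned `0..k-1`. Trials, labels and sampling
#' rate are unchanged. This is how reduced-montage configurations (e.g. the
#' three motor-cortex channels C3/Cz/C4 plus the EOG channels) are built.
#'
#' @param ds an `epoched_dataset`.
#' @param names channel names to keep (order respected).
#' @return An `epoched_dataset` with exactly the requested channels.
#' @examples
#' x <- array(rnorm(8 * 3 * 20), c(8, 3, 20))
#' ds <- epoched_dataset(x, rep(0:1, 4), c("C3", "Cz", "EOG0"),
#'                       c("EEG", "EEG", "EOG"), 250)
#' select_channels(ds, c("EOG0", "C3"))
#' @export
select_channels <- function(ds, names) {
  idx <- match(names, ds$channels$name)
  if (anyNA(idx))
    stop2("unknown channel name(s): ",
          paste(names[is.na(idx)], collapse = ", "),
          "\navailable: ", paste(ds$channels$name, collapse = ", "))
  out <- ds
  out$data <- ds$data[, idx, , drop = FALSE]
  out$channels <- data.frame(
    name = ds$channels$name[idx],
    modality = ds$channels$modality[idx],
    index = seq_along(idx) - 1L,
    stringsAsFactors = FALSE
  )
  out
}

subset_trials <- function(ds, idx) {
  out <- ds
  out$data <- ds$data[idx, , , drop = FALSE]
  out$labels <- ds$labels[idx]
  out
}

#' Split trials into train and test sets
#'
#' Random 80/20 (by default) partition of the trials. With
#' `stratified = TRUE` (default) the split is drawn per class so that class
#' proportions are preserved; the total training count equals
#' `round(train_fraction * n_trials)`, distributed over classes by largest
#' fractional remainder (ties broken by lowest class index).
#'
#' @param ds an `epoched_dataset`.
#' @param train_fraction fraction of trials for training, in (0, 1).
#' @param stratified draw the split within each class?
#' @param seed optional integer; the partition is deterministic given it.
#' @return A list with `train` and `test` (`epoched_dataset`s) and the
#'   integer index vectors `train_index`, `test_index` (disjoint,
#'   exhaustive).
#' @export
split_trials <- function(ds, train_fraction = 0.8, stratified = TRUE,
                         seed = NULL) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop2("`train_fraction` must be in (0, 1)")
  n <- n_trials(ds)
  target <- round(train_fraction * n)
  train_idx <- with_seed(seed, {
    if (!stratified) {
      sort(sample.int(n, target))
    } else {
      counts <- table(factor(ds$labels, levels = seq_len(n_classes(ds)) - 1L))
      if (any(counts < 2L))
        stop2("stratified split needs >= 2 trials per class; class(es) ",
              paste(names(counts)[counts < 2L], collapse = ", "), " too small")
      quota <- train_fraction * as.numeric(counts)
      base <- floor(quota)
      extra <- target - sum(base)
      take <- base
      if (extra > 0) {
        ord <- order(-(quota - base), seq_along(quota))
        take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
      }
      idx <- unlist(lapply(seq_along(take), function(k) {
        pool <- which(ds$labels == k - 1L)
        sample(pool, take[k])
      }))
      sort(idx)
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_trials(ds, train_idx),
       test = subset_trials(ds, test_idx),
       train_index = train_idx, test_index = test_idx)
}

#' Summary statistics for a column of per-subject accuracies
#'
#' Mean, median and standard deviation as used in the package's accuracy
#' tables: the median of an even count is the midpoint of the two central
#' values, and the standard deviation is the population form (divide by N,
#' not N-1) — the convention under which published per-subject accuracy
#' tables in this literature reproduce their printed summary rows.
#'
#' @param x numeric vector of accuracies in percent (length >= 1).
#' @return named numeric vector `c(mean, median, sd)`.
#' @examples
#' summarize_accuracy(c(79.3, 71.5, 83.6, 71.5, 95.6, 71.5, 92.2, 91.3, 90.5))
#' @export
summarize_accuracy <- function(x) {
  if (length(x) < 1L) stop2("need at least one accuracy value")
  if (any(!is.finite(x)) || any(x < 0 | x > 100))
    stop2("accuracies must be finite and in [0, 100]")
  m <- mean(x)
  c(mean = m, median = stats::median(x), sd = sqrt(mean((x - m)^2)))
}

#' Per-subject accuracy table
#'
#' Long-format table of per-subject accuracies keyed by configuration name,
#' with a `summary()` method computing the mean / median / population-SD
#' rows per configuration (see [summarize_accuracy()]).
#'
#' @param subject character/factor vector of subject ids.
#' @param configuration character vector of configuration names.
#' @param accuracy numeric vector of accuracies in percent.
#' @return object of class `accuracy_table` (a data frame).
#' @export
accuracy_table <- function(subject, configuration, accuracy) {
  rows <- data.frame(subject = as.character(subject),
                     configuration = as.character(configuration),
                     accuracy = as.numeric(accuracy),
                     stringsAsFactors = FALSE)
  if (any(rows$accuracy < 0 | rows$accuracy > 100))
    stop2("accuracies must be in [0, 100]")
  class(rows) <- c("accuracy_table", "data.frame")
  rows
}

#' @export
summary.accuracy_table <- function(object, ...) {
  configs <- unique(object$configuration)
  out <- t(vapply(configs, function(cf) {
    summarize_accuracy(object$accuracy[object$configuration == cf])
  }, numeric(3)))
  data.frame(configuration = configs, mean = out[, "mean"],
             median = out[, "median"], sd = out[, "sd"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export an accuracy table as CSV rows plus a JSON summary
#'
#' @param tab an `accuracy_table`.
#' @param csv_path path for the per-subject rows (CSV).
#' @param json_path path for the summary statistics (JSON).
#' @return invisibly, the summary data frame.
#' @export
write_accuracy_table <- function(tab, csv_path, json_path) {
  write.csv(as.data.frame(tab), csv_path, row.names = FALSE)
  s <- summary(tab)
  jsonlite::write_json(s, json_path, auto_unbox = TRUE, digits = NA)
  invisible(s)
}

#' Published per-subject accuracy tables
#'
#' The per-subject test accuracies reported for the two public
#' motor-imagery benchmarks (the 4-class, 22 EEG + 3 EOG competition
#' dataset, and the 7-class, 60 EEG + 2 EOG dataset) under five montage
#' configurations, shipped as package data. Used to validate the summary
#' conventions of [summarize_accuracy()] against print.
#'
#' @param dataset `"dataset1"` (9 subjects, 4 classes) or `"dataset2"`
#'   (10 subjects, 7 classes).
#' @return A data frame of per-subject accuracies (percent), one column per
#'   configuration, plus attribute `"printed_summary"`: the published
#'   mean/median/SD cells as printed.
#' @export
published_results <- function(dataset = c("dataset1", "dataset2")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0(dataset, "_accuracy.csv"),
                      package = "mieog")
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  summary_rows <- df$subject %in% c("Mean", "Median", "StandardDeviation")
  printed <- df[summary_rows, , drop = FALSE]
  out <- df[!summary_rows, , drop = FALSE]
  attr(out, "printed_summary") <- printed
  out
}
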