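test_that("dataset validation reports inconsistencies", {
  x <- array(rnorm(8 * 2 * 10), c(8, 2, 10))
  expect_s3_class(epoched_dataset(x, rep(0:1, 4), c("a", "b"), "EEG", 100),
                  "epoched_dataset")
  expect_error(epoched_dataset(x, rep(0:1, 3), c("a", "b"), "EEG", 100),
               "labels length")
  expect_error(epoched_dataset(x, rep(0:1, 4), c("a", "a"), "EEG", 100),
               "not unique")
  expect_error(epoched_dataset(x, rep(0:1, 4), c("a", "b"), "EEG", -1),
               "sampling_rate")
  expect_error(epoched_dataset(x, rep(0:3, 2), c("a", "b"), "EEG", 100,
                               class_names = paste0("k", 1:5)),
               "no trials")
})

test_that("select_channels returns exactly the named channels in order", {
  ds <- toy_dataset(channels = c("C3", "Cz", "C4", "EOG0", "EOG1", "EOG2"))
  # identity selection
  same <- select_channels(ds, ds$channels$name)
  expect_identical(same$data, ds$data)
  expect_identical(same$channels, ds$channels)
  # the reduced six-channel montage: three EEG + three EOG
  red <- select_channels(ds, c("C3", "Cz", "C4", "EOG0", "EOG1", "EOG2"))
  expect_identical(dim(red$data)[2], 6L)
  expect_identical(sum(red$channels$modality == "EEG"), 3L)
  expect_identical(sum(red$channels$modality == "EOG"), 3L)
  # order respected, indices reassigned
  rev2 <- select_channels(ds, c("EOG1", "C4"))
  expect_identical(rev2$channels$name, c("EOG1", "C4"))
  expect_identical(rev2$channels$index, 0:1)
  expect_identical(rev2$data[, 1, ], ds$data[, 5, ])
  # unknown channel named in the error, with available names listed
  expect_error(select_channels(ds, "NOPE"), "NOPE")
  expect_error(select_channels(ds, "NOPE"), "available")
})

test_that("nested channel selections compose", {
  ds <- toy_dataset(channels = c("C3", "Cz", "C4", "EOG0", "EOG1"))
  outer <- select_channels(ds, c("Cz", "C4", "EOG1"))
  inner <- select_channels(outer, c("EOG1", "Cz"))
  direct <- select_channels(ds, c("EOG1", "Cz"))
  expect_identical(inner$data, direct$data)
  expect_identical(inner$channels, direct$channels)
})

test_that("split_trials partitions trials with stratified class balance", {
  ds <- toy_dataset(n_trials = 100, n_classes = 4)
  sp <- split_trials(ds, 0.8, stratified = TRUE, seed = 11)
  expect_length(sp$train_index, 80)
  expect_length(sp$test_index, 20)
  expect_identical(sort(c(sp$train_index, sp$test_index)), 1:100)
  expect_identical(as.integer(table(sp$train$labels)), rep(20L, 4))
  expect_identical(as.integer(table(sp$test$labels)), rep(5L, 4))
  # deterministic given seed
  sp2 <- split_trials(ds, 0.8, stratified = TRUE, seed = 11)
  expect_identical(sp$train_index, sp2$train_index)
  # a class with < 2 trials cannot be stratified
  x <- array(rnorm(5 * 2 * 8), c(5, 2, 8))
  ds_bad <- epoched_dataset(x, c(0L, 0L, 0L, 0L, 1L), c("a", "b"), "EEG", 100)
  expect_error(split_trials(ds_bad, 0.8, stratified = TRUE), "2 trials")
})

test_that("large stratified split allocates the rounded total by remainder", {
  # 576 trials, 4 classes of 144: round(0.8 * 576) = 461 in train,
  # distributed 116/115/115/115 by largest remainder (tie -> class 0)
  x <- array(0, c(576, 1, 2))
  x[, 1, 1] <- rnorm(576)
  x[, 1, 2] <- rnorm(576)
  ds <- epoched_dataset(x, rep(0:3, each = 144), "only", "EEG", 250)
  sp <- split_trials(ds, 0.8, stratified = TRUE, seed = 5)
  expect_length(sp$train_index, 461)
  expect_length(sp$test_index, 115)
  expect_identical(as.integer(table(sp$train$labels)), c(116L, 115L, 115L, 115L))
})

test_that("non-stratified split honours the total count", {
  ds <- toy_dataset(n_trials = 30)
  sp <- split_trials(ds, 0.8, stratified = FALSE, seed = 2)
  expect_length(sp$train_index, 24)
  expect_identical(sort(c(sp$train_index, sp$test_index)), 1:30)
})

test_that("summarize_accuracy uses midpoint median and population SD", {
  # single value: degenerate case
  expect_equal(unname(summarize_accuracy(73.1)), c(73.1, 73.1, 0))
  # even count: median is the midpoint of the two central values
  s <- summarize_accuracy(c(50, 58, 66, 90))
  expect_equal(unname(s["median"]), 62)
  # population SD (divide by N), not the sample form
  v <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_equal(unname(summarize_accuracy(v)["sd"]), 2)  # known pop-SD example
  expect_error(summarize_accuracy(numeric(0)), "at least one")
  expect_error(summarize_accuracy(c(50, 120)), "\\[0, 100\\]")
})

test_that("accuracy tables summarize per configuration and export", {
  tab <- accuracy_table(rep(c("S1", "S2"), 2),
                        rep(c("all", "reduced"), each = 2),
                        c(80, 70, 85, 75))
  s <- summary(tab)
  expect_identical(s$configuration, c("all", "reduced"))
  expect_equal(s$mean, c(75, 80))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_accuracy_table(tab, csv, js)
  expect_equal(nrow(read.csv(csv)), 4)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$mean, c(75, 80))
})

test_that("published accuracy tables load with their printed summaries", {
  for (d in c("dataset1", "dataset2")) {
    df <- published_results(d)
    printed <- attr(df, "printed_summary")
    expect_identical(nrow(df), if (d == "dataset1") 9L else 10L)
    expect_identical(printed$subject,
                     c("Mean", "Median", "StandardDeviation"))
    expect_identical(ncol(df), 6L)  # subject + 5 configurations
    expect_true(all(sapply(df[-1], is.numeric)))
  }
})
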