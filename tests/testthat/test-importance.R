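# A minimal classifier handle for exercising permutation importance:
# predicts from the sign of the mean of the channels listed in `use`,
# ignoring all others.
mock_mean_model <- function(use, channels) {
  structure(list(use = use, channels = channels), class = "mock_mean_model")
}
predict.mock_mean_model <- function(object, newdata, ...) {
  m <- apply(newdata$data[, object$use, , drop = FALSE], 1, mean)
  as.integer(m > 0)
}
registerS3method("predict", "mock_mean_model", predict.mock_mean_model)

test_that("rankings sort scores descending with index tie-break", {
  ch <- data.frame(name = paste0("c", 1:5),
                   modality = rep("EEG", 5), index = 0:4)
  imp <- new_importance("csp_pattern", c(0.2, 0.9, 0.2, 0.5, NA), ch)
  expect_identical(imp$ranking, c(2L, 4L, 1L, 3L, 5L))
  expect_identical(top_channels(imp, 2), c("c2", "c4"))
  rank_col <- write_importance_csv(imp, tempfile())$rank
  expect_identical(rank_col, c(3L, 1L, 4L, 2L, 5L))
})

test_that("permutation importance is zero for ignored or constant channels", {
  ds <- toy_dataset(n_trials = 24, channels = c("a", "b", "c"))
  ds$data[, 3, ] <- 1  # constant channel: permutation is a no-op
  model <- mock_mean_model(use = 1L, channels = ds$channels)
  imp <- permutation_importance(model, ds, n_repeats = 4, seed = 1)
  expect_identical(unname(imp$scores["b"]), 0)  # model ignores b entirely
  expect_identical(unname(imp$scores["c"]), 0)  # constant channel
  expect_identical(imp$metadata$baseline_accuracy,
                   mean(predict(model, ds) == ds$labels))
})

test_that("permutation importance finds the channel the model relies on", {
  set.seed(4)
  n <- 60
  x <- array(rnorm(n * 3 * 32), c(n, 3, 32))
  y <- rep(0:1, each = n / 2)
  x[y == 1, 2, ] <- x[y == 1, 2, ] + 2   # channel 2 carries the labels
  ds <- epoched_dataset(x, y, c("a", "b", "c"), "EEG", 64)
  model <- mock_mean_model(use = 2L, channels = ds$channels)
  imp <- permutation_importance(model, ds, n_repeats = 6, seed = 2)
  expect_identical(top_channels(imp, 1), "b")
  expect_gt(imp$scores["b"], 0.2)
  # deterministic given the seed
  imp2 <- permutation_importance(model, ds, n_repeats = 6, seed = 2)
  expect_identical(imp$scores, imp2$scores)
})

test_that("permutation importance rejects a channel-count mismatch", {
  ds <- toy_dataset(channels = c("a", "b", "c"))
  model <- mock_mean_model(1L, ds$channels)
  expect_error(permutation_importance(model, toy_dataset(channels = c("a", "b")),
                                      n_repeats = 2),
               "channels")
})

test_that("subset scores are occurrence means (worked 3-channel example)", {
  sc <- channel_subset_scores(list(c(1, 2), c(2, 3), c(1, 3)),
                              c(0.6, 0.8, 0.7), 3)
  expect_equal(sc, c(0.65, 0.70, 0.75))
  # invariant to the order of the evaluated subsets
  sc2 <- channel_subset_scores(list(c(1, 3), c(1, 2), c(2, 3)),
                               c(0.7, 0.6, 0.8), 3)
  expect_equal(sc2, sc)
  # unseen channel flagged as NA, not silently zero
  sc3 <- channel_subset_scores(list(c(1, 2)), 0.9, 3)
  expect_true(is.na(sc3[3]))
})

test_that("random search scores constant trainers uniformly", {
  ds <- toy_dataset(n_trials = 12, channels = paste0("c", 1:4))
  rs <- random_search(ds, subset_size = 2, n_iterations = 40,
                      trainer = function(d) 0.7, seed = 3)
  expect_equal(unname(rs$scores), rep(0.7, 4))
})

test_that("random search elevates a planted channel under an oracle trainer", {
  ds <- toy_dataset(n_trials = 12, channels = paste0("c", 1:6))
  oracle <- function(d) if ("c3" %in% d$channels$name) 1.0 else 0.5
  rs <- random_search(ds, subset_size = 3, n_iterations = 60,
                      trainer = oracle, seed = 5)
  expect_identical(unname(rs$scores["c3"]), 1.0)
  expect_true(all(rs$scores[setdiff(names(rs$scores), "c3")] < 1.0))
  expect_identical(top_channels(rs, 1), "c3")
})

test_that("random search flags never-selected channels and validates input", {
  ds <- toy_dataset(n_trials = 8, channels = paste0("c", 1:6))
  expect_warning(rs <- random_search(ds, subset_size = 2, n_iterations = 1,
                                     trainer = function(d) 0.5, seed = 1),
                 "never selected")
  expect_identical(sum(is.na(rs$scores)), 4L)
  expect_error(random_search(ds, subset_size = 9, n_iterations = 5,
                             trainer = function(d) 0.5),
               "exceeds")
})

test_that("random search is reproducible given its seed", {
  ds <- toy_dataset(n_trials = 16, channels = paste0("c", 1:5))
  trainer <- make_bandpower_trainer(band = c(10, 30))
  a <- random_search(ds, subset_size = 2, n_iterations = 10,
                     trainer = trainer, seed = 9)
  b <- random_search(ds, subset_size = 2, n_iterations = 10,
                     trainer = trainer, seed = 9)
  expect_identical(a$scores, b$scores)
})
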