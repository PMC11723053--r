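test_that("identical class covariances give unit eigenvalues", {
  ds <- toy_dataset(n_trials = 40, channels = paste0("ch", 1:3),
                    n_samples = 128, seed = 2)
  # same trials in both classes: covariances match exactly
  ds$data[ds$labels == 1, , ] <- ds$data[ds$labels == 0, , ]
  fit <- csp_fit(ds, 0, 1, reg = 0)
  expect_lt(max(abs(fit$eigenvalues_lambda - 1)), 1e-6)
})

test_that("the two-channel contrast toy is solved exactly", {
  ds <- csp_toy_dataset()
  fit <- csp_fit(ds, 0, 1, reg = 0)
  expect_equal(fit$eigenvalues_lambda, c(4, 0.25), tolerance = 1e-9)
  # filters aligned with the coordinate axes
  w1 <- abs(fit$filters_w[, 1]) / max(abs(fit$filters_w[, 1]))
  expect_equal(unname(w1), c(1, 0), tolerance = 1e-9)
  # swapping the classes inverts eigenvalues and reverses filter order
  swp <- csp_fit(ds, 1, 0, reg = 0)
  expect_equal(swp$eigenvalues_lambda, rev(1 / fit$eigenvalues_lambda),
               tolerance = 1e-9)
})

test_that("eigenvalues satisfy the generalized eigenproblem and pattern duality", {
  ds <- toy_dataset(n_trials = 60, channels = paste0("ch", 1:4),
                    n_samples = 200, seed = 7)
  ds$data[ds$labels == 1, 2, ] <- ds$data[ds$labels == 1, 2, ] * 2
  fit <- csp_fit(ds, 0, 1)
  S <- mieog:::class_cov(ds, which(ds$labels == 0)) + 1e-6 * diag(4)
  R <- mieog:::class_cov(ds, which(ds$labels == 1)) + 1e-6 * diag(4)
  W <- fit$filters_w
  resid <- S %*% W - R %*% W %*% diag(fit$eigenvalues_lambda)
  expect_lt(max(abs(resid)), 1e-8)
  expect_lt(max(abs(t(fit$patterns) %*% W - diag(4))), 1e-6)
})

test_that("eigenvalues match the dense-grid Rayleigh-quotient oracle", {
  set.seed(11)
  for (C in 2:3) {
    ds <- toy_dataset(n_trials = 40, channels = paste0("ch", 1:C),
                      n_samples = 150, seed = C)
    ds$data[ds$labels == 0, 1, ] <- ds$data[ds$labels == 0, 1, ] * 1.8
    fit <- csp_fit(ds, 0, 1)
    S <- mieog:::class_cov(ds, which(ds$labels == 0)) + 1e-6 * diag(C)
    R <- mieog:::class_cov(ds, which(ds$labels == 1)) + 1e-6 * diag(C)
    grid_max <- rayleigh_grid_max(S, R, n_grid = if (C == 2) 2000 else 250)
    expect_lt(abs(grid_max - fit$eigenvalues_lambda[1]) /
                fit$eigenvalues_lambda[1], 0.01)
  }
})

test_that("projection variance ratios reproduce the eigenvalues", {
  set.seed(13)
  C <- 3
  ds <- toy_dataset(n_trials = 200, channels = paste0("ch", 1:C),
                    n_samples = 250, seed = 5)
  ds$data[ds$labels == 0, 2, ] <- ds$data[ds$labels == 0, 2, ] * 1.6
  fit <- csp_fit(ds, 0, 1)
  # trace-normalized projected power per trial, averaged within class:
  # exactly w' S w (resp. w' R w), so the ratio estimates lambda_j
  proj_power <- function(idx, w) {
    mean(apply(ds$data[idx, , ], 1, function(X) {
      X <- matrix(X, nrow = C)
      sum((w %*% X)^2) / sum(X^2)
    }))
  }
  for (j in c(1, C)) {
    w <- fit$filters_w[, j]
    ratio <- proj_power(which(ds$labels == 0), w) /
      proj_power(which(ds$labels == 1), w)
    expect_lt(abs(ratio - fit$eigenvalues_lambda[j]) /
                fit$eigenvalues_lambda[j], 0.05)
  }
})

test_that("missing classes and degenerate covariances are rejected", {
  ds <- toy_dataset(n_trials = 20, channels = c("a", "b"))
  expect_error(csp_fit(ds, 5, 1), "no trials")
  dup <- ds
  dup$data[, 2, ] <- dup$data[, 1, ]  # rank-deficient covariance
  expect_error(csp_fit(dup, 0, 1, reg = 0), "singular|shrinkage")
})

test_that("pattern activations score the contrast-carrying channel highest", {
  ds <- csp_toy_dataset()
  fit <- csp_fit(ds, 0, 1, reg = 0)
  imp <- csp_pattern_activation(fit, n_patterns = 1)
  expect_identical(top_channels(imp, 1), "chA")
  expect_identical(dim(imp$metadata$activations), c(1L, 2L))
  expect_error(csp_pattern_activation(fit, n_patterns = 5), "exceeds")
})

test_that("orthonormal filters make patterns equal filters", {
  # when W is orthonormal, (W^-1)' = W, so activations = |filter entries|
  ds <- toy_dataset(n_trials = 30, channels = paste0("ch", 1:3),
                    n_samples = 100, seed = 3)
  fit <- csp_fit(ds, 0, 1)
  Q <- qr.Q(qr(fit$filters_w))      # orthonormalized stand-in
  fit$filters_w <- Q
  fit$patterns <- t(solve(Q))
  expect_equal(fit$patterns, Q, tolerance = 1e-10)
})

test_that("one-vs-rest drives the multi-class importance ranking", {
  cfg <- sim_config(layout = "custom", n_eeg = 4L, n_eog = 1L,
                    n_classes = 3L, n_trials = 90L, n_samples = 200L,
                    sampling_rate = 100,
                    informative_channels = c("EEG1", "EEG3"),
                    modulation_depth = 0.8, eog_leakage = 0,
                    artifact_rate = 0, seed = 17)
  sim <- simulate_dataset(cfg)
  imp <- csp_importance(sim$dataset, n_patterns = 4)
  expect_true(all(c("EEG1", "EEG3") %in% top_channels(imp, 3)))
})
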