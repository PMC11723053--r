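# Experiment drivers for the planted-structure recovery study: the
# package's desk-scale evidence that each importance method finds the
# channels that actually carry class information.

#' Planted-channel recovery experiment across seeds
#'
#' For each seed, simulates the planted four-class preset
#' ([sim_config_planted()]) and asks whether each importance method ranks
#' all three planted channels within its top 5 of 12: CSP pattern
#' activations, random search with the band-power LDA trainer, permutation
#' importance of a band-power LDA classifier fitted on the train split and
#' permuted on the held-out split, and ensemble-averaged attention gates.
#' The label-free MI matrix is not part of this recovery check (it
#' measures channel-channel, not channel-class, dependence).
#'
#' The attention score is the gate value averaged over the whole recording
#' and over a small ensemble of short trainings (by default 5 networks x
#' 20 epochs), each on its own random split and initialization, on
#' band-pass-filtered (7-35 Hz) data: a single model's gates reflect which
#' of several equally usable channels that particular run latched onto,
#' and the ensemble mean over splits and initializations removes that
#' run-level noise. Filtering concentrates the network on the band where
#' the planted effects live.
#'
#' @param seeds integer vector of simulation/training seeds.
#' @param epochs CNN training epochs per ensemble member (default 20).
#' @param ensemble number of attention networks averaged per seed
#'   (default 5).
#' @param top_k rank cutoff (default 5).
#' @param rs_iterations random-search iterations (default 150 draws of
#'   5 channels).
#' @param perm_repeats permutations per channel (default 10).
#' @param verbose print one line per seed?
#' @return data frame with one row per seed and a logical column per
#'   method (`csp`, `permutation`, `attention`, `random_search`): TRUE if
#'   all planted channels ranked in the top `top_k`. Attribute
#'   `"peak_accuracy"` holds the per-seed mean network peak test
#'   accuracy (%).
#' @export
recovery_experiment <- function(seeds = 1:10, epochs = 20L, ensemble = 5L,
                                top_k = 5L, rs_iterations = 150L,
                                perm_repeats = 10L, verbose = FALSE) {
  res <- data.frame(seed = seeds, csp = FALSE, permutation = FALSE,
                    attention = FALSE, random_search = FALSE)
  peaks <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    sim <- simulate_dataset(sim_config_planted(seed = s))
    planted <- sim$truth$informative_channels
    hit <- function(imp) all(planted %in% top_channels(imp, top_k))

    filtered <- bandpass_filter(sim$dataset, 7, 35)
    res$csp[i] <- hit(csp_importance(sim$dataset, n_patterns = 5L))
    rs <- random_search(sim$dataset, subset_size = 5L,
                        n_iterations = rs_iterations,
                        trainer = make_bandpower_trainer(), seed = s)
    res$random_search[i] <- hit(rs)

    sp <- split_trials(sim$dataset, 0.8, stratified = TRUE, seed = s)
    lda <- bandpower_classifier(sp$train)
    res$permutation[i] <- hit(permutation_importance(lda, sp$test,
                                                     n_repeats = perm_repeats,
                                                     seed = s))

    gates <- 0
    peak <- 0
    for (m in seq_len(ensemble)) {
      spf <- split_trials(filtered, 0.8, stratified = TRUE,
                          seed = s * 100L + m)
      fit <- micnn(spf$train, test = spf$test, attention = TRUE,
                   filters_per_kernel = 8L, pool_size = 16L,
                   batch_size = 16L, lr = 2e-3, dropout = 0.25,
                   epochs = epochs, seed = s * 100L + m)
      gates <- gates + attention_importance(fit, filtered)$scores
      peak <- peak + fit$peak_test_accuracy
    }
    peaks[i] <- peak / ensemble
    att <- new_importance("attention", gates / ensemble, filtered$channels,
                          metadata = list(ensemble = ensemble,
                                          epochs = epochs))
    res$attention[i] <- hit(att)
    if (verbose)
      message(sprintf(
        "seed %d: csp %s perm %s att %s rs %s (net peak %.1f%%)", s,
        res$csp[i], res$permutation[i], res$attention[i],
        res$random_search[i], peaks[i]))
  }
  attr(res, "peak_accuracy") <- peaks
  res
}

#' EOG-only classification under neural leakage
#'
#' Simulates the leakage preset ([sim_config_leakage()]), restricts the
#' recording to its EOG channels alone, and evaluates the band-power LDA
#' classifier on a stratified 80/20 split. Each EOG channel leaks a
#' different planted source, so the ocular montage alone carries
#' class-separating signal; the returned record includes the binomial
#' chance level and its standard error at the test size for the
#' above-chance comparison.
#'
#' @param seed integer seed for simulation and split.
#' @return list with `accuracy` (fraction), `chance`, `se` (binomial SE of
#'   chance at the test-set size), and `n_test`.
#' @export
eog_only_experiment <- function(seed = 1L) {
  sim <- simulate_dataset(sim_config_leakage(seed = seed))
  eog <- select_channels(sim$dataset, channels_of(sim$dataset, "EOG"))
  sp <- split_trials(eog, 0.8, stratified = TRUE, seed = seed)
  model <- bandpower_classifier(sp$train)
  acc <- classification_accuracy(model, sp$test)
  chance <- 1 / n_classes(eog)
  n_test <- n_trials(sp$test)
  list(accuracy = acc, chance = chance,
       se = sqrt(chance * (1 - chance) / n_test), n_test = n_test)
}
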