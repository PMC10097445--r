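# Shared fixtures, built lazily so only the tests that need them pay the
# training cost.

.fixture_env <- new.env(parent = emptyenv())

# Small labelled cohort (5 subjects, 10 s per activity) and its features.
tiny_features <- function() {
  if (is.null(.fixture_env$feats)) {
    cohort <- simulate_cohort(5, duration_per_activity = 10, seed = 11)
    .fixture_env$feats <- lapply(cohort, preprocess_labeled)
  }
  .fixture_env$feats
}

# A model trained on all five tiny-cohort subjects.
tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    all_feats <- chestmotion:::combine_features(tiny_features())
    .fixture_env$model <- har_lstm(
      all_feats, config = lstm_config(max_epochs = 500, seed = 5))
  }
  .fixture_env$model
}

# A model trained to convergence on the separable pure-tone classes.
separable_model <- function() {
  if (is.null(.fixture_env$sep_model)) {
    .fixture_env$sep_feats <- separable_features(n_per = 20)
    # the fixture set is tiny (4 minibatches/epoch), so a larger step size
    # compensates for the small number of updates per epoch
    .fixture_env$sep_model <- har_lstm(
      .fixture_env$sep_feats,
      config = lstm_config(max_epochs = 400, learning_rate = 0.01,
                           seed = 2))
  }
  list(model = .fixture_env$sep_model, feats = .fixture_env$sep_feats)
}

# Six linearly separable synthetic classes: class k concentrates spectral
# energy in bin k on a class-specific axis. n_per windows per class.
separable_features <- function(n_per = 20, seed = 3) {
  chestmotion:::with_seed(seed, {
    labels <- rep(activity_levels(), each = n_per)
    n <- length(labels)
    arr <- array(abs(rnorm(n * 11 * 3, 0, 0.05)), dim = c(n, 11, 3))
    for (k in seq_along(activity_levels())) {
      idx <- which(labels == activity_levels()[k])
      arr[idx, k + 1, (k - 1) %% 3 + 1] <-
        10 + rnorm(length(idx), 0, 0.2)
    }
    structure(list(spectra = arr, bin_hz = 0.5, width = 20L,
                   labels = chestmotion:::as_activity_factor(labels),
                   start_index = seq_len(n) - 1L,
                   subject_id = rep("synthetic", n)),
              class = "feature_set")
  })
}
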