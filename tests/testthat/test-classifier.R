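# LSTM core correctness (finite-difference oracle) and classifier
# behaviour: determinism, separability, prediction contracts, confusion
# matrices and leave-one-subject-out folds.

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- lstm_config(input_channels = 2, hidden1 = 3, hidden2 = 4,
                     n_classes = 3, dropout_p = 0, minibatch = 2,
                     max_epochs = 1)
  params <- chestmotion:::init_lstm_params(cfg)
  B <- 4; T <- 5; D <- 2
  X <- array(rnorm(B * D * T), dim = c(B, D, T))
  y <- c(1L, 2L, 3L, 1L)
  res <- chestmotion:::lstm_loss_grad(X, y, params, 0, FALSE)
  numeric_grad <- function(nm, i) {
    eps <- 1e-6
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
    (chestmotion:::lstm_loss_grad(X, y, p1, 0, FALSE)$loss -
       chestmotion:::lstm_loss_grad(X, y, p2, 0, FALSE)$loss) / (2 * eps)
  }
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(6, length(params[[nm]])))
    for (i in idx) {
      expect_equal(res$grads[[nm]][i], numeric_grad(nm, i),
                   tolerance = 1e-5)
    }
  }
})

test_that("training is deterministic given the seed", {
  feats <- separable_features(n_per = 6)
  cfg <- lstm_config(max_epochs = 5, seed = 7)
  m1 <- har_lstm(feats, config = cfg)
  m2 <- har_lstm(feats, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  m3 <- har_lstm(feats, config = lstm_config(max_epochs = 5, seed = 8))
  expect_false(identical(m1$params, m3$params))
})

test_that("six separable pure-tone classes are learned to 100%", {
  sep <- separable_model()
  feats <- sep$feats
  cm <- evaluate_classifier(sep$model, feats)
  expect_equal(accuracy(cm), 1.0)
  expect_true(all(diag(unclass(cm)) == 20))
})

test_that("prediction contracts hold", {
  feats <- separable_features(n_per = 5)
  model <- har_lstm(feats, config = lstm_config(max_epochs = 10, seed = 1))
  probs <- predict(model, feats, type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  # inference is a pure function (dropout off)
  expect_identical(predict(model, feats), predict(model, feats))
  # forced tie resolves to the first canonical class
  uniform <- matrix(1 / 6, 2, 6)
  expect_equal(as.character(prob_to_label(uniform)), c("walk", "walk"))
  # shape mismatch rejected
  bad <- array(0, dim = c(3, 11, 2))
  expect_error(predict(model, bad), "channel")
})

test_that("confusion matrices conserve mass and orient rows as predictions", {
  sep <- separable_model()
  feats <- sep$feats
  model <- sep$model
  cm <- evaluate_classifier(model, feats)
  expect_equal(sum(cm), length(feats$labels))
  expect_equal(accuracy(cm), sum(diag(unclass(cm))) / sum(cm))
  empty <- feats
  empty$spectra <- feats$spectra[integer(0), , , drop = FALSE]
  empty$labels <- feats$labels[integer(0)]
  expect_error(evaluate_classifier(model, empty), "empty")
})

test_that("accuracy equals mean per-class recall only for balanced counts", {
  # hand-computed 2x2 counterexample embedded in a 6x6 matrix:
  # class walk: 90 correct of 100; class still: 5 correct of 10
  cm <- matrix(0L, 6, 6, dimnames = list(activity_levels(),
                                         activity_levels()))
  cm["walk", "walk"] <- 90L; cm["still", "walk"] <- 10L
  cm["still", "still"] <- 5L; cm["walk", "still"] <- 5L
  acc <- accuracy(cm)
  recalls <- c(90 / 100, 5 / 10)
  expect_equal(acc, 95 / 110)
  expect_false(isTRUE(all.equal(acc, mean(recalls))))
  # balanced case (10 windows per actual class): equality
  cm2 <- matrix(0L, 6, 6)
  diag(cm2) <- 10L
  cm2[1, 1] <- 8L; cm2[2, 2] <- 8L; cm2[1, 2] <- 2L; cm2[2, 1] <- 2L
  per_class <- diag(cm2) / colSums(cm2)
  expect_equal(sum(diag(cm2)) / sum(cm2), mean(per_class))
})

test_that("LOSO folds partition subjects and average fold accuracies", {
  feats <- tiny_features()
  res <- loso_cv(feats, lstm_config(max_epochs = 3, seed = 9))
  expect_equal(length(res$fold_accuracy), 5L)
  expect_equal(res$mean_accuracy, mean(res$fold_accuracy))
  for (id in names(feats)) {
    expect_equal(sum(res$confusion[[id]]), nrow(feats[[id]]$spectra))
  }
  expect_error(loso_cv(feats[1], lstm_config()), "at least 2")
})

test_that("the printed per-fold accuracies average as stated", {
  expect_equal(mean(c(81.8, 78.8, 87.0, 83.3, 88.1)), 83.8)
})

test_that("training rejects degenerate inputs", {
  feats <- separable_features(n_per = 4)
  only_two <- feats
  keep <- feats$labels %in% c("walk", "still")
  only_two$spectra <- feats$spectra[keep, , , drop = FALSE]
  only_two$labels <- droplevels(feats$labels[keep])
  expect_error(har_lstm(structure(list(
    spectra = only_two$spectra, width = 20L,
    labels = chestmotion:::as_activity_factor(as.character(only_two$labels)),
    bin_hz = 0.5), class = "feature_set")), "classes")
  expect_error(har_lstm(feats, labels = feats$labels[-1]), "length|classes")
})
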