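# The six-class chest-movement classifier: a compact two-layer LSTM
# (20 then 30 hidden units, dropout 0.1 between the layers, dense softmax
# head on the last time step) trained by stochastic gradient descent with
# momentum on one-sided magnitude spectra (11 bins x 3 axis channels).

#' LSTM classifier configuration
#'
#' Architecture and optimiser settings. Defaults are the reference
#' configuration: 3 input channels, stacked recurrent layers of 20 and 30
#' units with a dropout layer (p = 0.1) between them, 6 output classes,
#' minibatch 30, 300 epochs, SGD with learning rate 0.001 and momentum 0.9.
#'
#' @param input_channels Number of input channels per time step.
#' @param hidden1,hidden2 Hidden units of the first and second LSTM layers.
#' @param dropout_p Dropout probability between the layers, in `[0, 1)`.
#' @param n_classes Number of output classes.
#' @param minibatch Minibatch size.
#' @param max_epochs Training epochs (no early stopping).
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(input_channels = 3L, hidden1 = 20L, hidden2 = 30L,
                        dropout_p = 0.1, n_classes = 6L, minibatch = 30L,
                        max_epochs = 300L, learning_rate = 0.001,
                        momentum = 0.9, seed = 1L) {
  cfg <- list(input_channels = as.integer(input_channels),
              hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
              dropout_p = dropout_p, n_classes = as.integer(n_classes),
              minibatch = as.integer(minibatch),
              max_epochs = as.integer(max_epochs),
              learning_rate = learning_rate, momentum = momentum,
              seed = as.integer(seed))
  sizes <- c(cfg$input_channels, cfg$hidden1, cfg$hidden2, cfg$n_classes,
             cfg$minibatch, cfg$max_epochs)
  if (any(sizes < 1L)) stop("all sizes must be positive", call. = FALSE)
  if (cfg$dropout_p < 0 || cfg$dropout_p >= 1) {
    stop("dropout_p must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  class(cfg) <- "lstm_config"
  cfg
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# Initialise weights; forget-gate biases start at 1 (standard for small
# LSTMs, keeps early memory open).
init_lstm_params <- function(cfg) {
  D <- cfg$input_channels; H1 <- cfg$hidden1; H2 <- cfg$hidden2
  K <- cfg$n_classes
  forget_bias <- function(H) {
    b <- numeric(4 * H); b[(H + 1):(2 * H)] <- 1; b
  }
  list(W1 = glorot(D, 4 * H1), U1 = glorot(H1, 4 * H1), b1 = forget_bias(H1),
       W2 = glorot(H1, 4 * H2), U2 = glorot(H2, 4 * H2),
       b2 = forget_bias(H2),
       Wd = glorot(H2, K), bd = numeric(K))
}

# Coerce features (feature_set or raw array n x T x D) into the B x D x T
# cube layout of the compiled core, applying the fixed input scaling
# 1/width so spectra magnitudes enter at O(1) amplitude units.
features_to_cube <- function(features, scale) {
  arr <- if (inherits(features, "feature_set")) features$spectra else features
  if (length(dim(arr)) != 3L) {
    stop("features must be an n x timesteps x channels array", call. = FALSE)
  }
  aperm(arr * scale, c(1, 3, 2))
}

feature_labels <- function(features, labels) {
  if (is.null(labels) && inherits(features, "feature_set")) {
    labels <- features$labels
  }
  if (is.null(labels)) stop("labels are required for training", call. = FALSE)
  as_activity_factor(labels)
}

#' Fit the two-layer LSTM chest-movement classifier
#'
#' Trains the network on per-window magnitude spectra with softmax
#' cross-entropy loss and SGD-with-momentum, running the full epoch budget
#' (no early stopping). Training is fully reproducible: initialisation,
#' epoch shuffling and dropout all derive from `config$seed`.
#'
#' @param features A `feature_set` from [spectral_features()] /
#'   [preprocess_stream()], or a numeric array `n x timesteps x channels`.
#' @param labels Per-window labels; taken from the `feature_set` if omitted.
#' @param config An [lstm_config()].
#' @return An object of class `har_lstm`: learned weights, the config, the
#'   canonical class ordering and a per-epoch training history
#'   (`epoch`, `loss`, `accuracy`).
#' @seealso [predict.har_lstm()], [evaluate_classifier()], [loso_cv()]
#' @export
har_lstm <- function(features, labels = NULL, config = lstm_config()) {
  y <- feature_labels(features, labels)
  if (nlevels(droplevels(y)) < config$n_classes) {
    stop("training data must contain all ", config$n_classes, " classes",
         call. = FALSE)
  }
  width <- if (inherits(features, "feature_set")) features$width else 20L
  scale <- 1 / width
  cube <- features_to_cube(features, scale)
  if (dim(cube)[2] != config$input_channels) {
    stop("feature channel count does not match config$input_channels",
         call. = FALSE)
  }
  n <- dim(cube)[1]
  if (length(y) != n) stop("labels length must match window count",
                           call. = FALSE)
  y_int <- as.integer(y)

  with_seed(config$seed, {
    params <- init_lstm_params(config)
    velocity <- lapply(params, function(p) p * 0)
    history <- data.frame(epoch = seq_len(config$max_epochs),
                          loss = NA_real_, accuracy = NA_real_)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- c(); hits <- 0L
      for (start in seq(1, n, by = config$minibatch)) {
        idx <- ord[start:min(start + config$minibatch - 1L, n)]
        xb <- cube[idx, , , drop = FALSE]
        res <- lstm_loss_grad(xb, y_int[idx], params, config$dropout_p, TRUE)
        g <- res$grads
        for (nm in names(params)) {
          gm <- g[[nm]]
          if (is.null(dim(params[[nm]]))) gm <- as.numeric(gm)
          velocity[[nm]] <- config$momentum * velocity[[nm]] -
            config$learning_rate * gm
          params[[nm]] <- params[[nm]] + velocity[[nm]]
        }
        losses <- c(losses, res$loss)
        hits <- hits + sum(max.col(res$probs, ties.method = "first") ==
                             y_int[idx])
      }
      history$loss[epoch] <- mean(losses)
      history$accuracy[epoch] <- hits / n
    }
    structure(
      list(params = params, config = config, classes = activity_levels(),
           input_scale = scale, history = history),
      class = "har_lstm"
    )
  })
}

#' @export
print.har_lstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Two-layer LSTM chest-movement classifier (%d -> %d -> %d -> %d)\n",
    cfg$input_channels, cfg$hidden1, cfg$hidden2, cfg$n_classes))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  trained %d epochs; final loss %.4f, training accuracy %.1f%%\n",
              cfg$max_epochs, last$loss, 100 * last$accuracy))
  invisible(x)
}

#' Predict movement classes for feature windows
#'
#' Inference is deterministic (dropout disabled). Class is the argmax of the
#' softmax probabilities; exact ties resolve to the earliest class in the
#' canonical order.
#'
#' @param object A fitted [har_lstm()] model.
#' @param newdata A `feature_set` or `n x timesteps x channels` array.
#' @param type `"class"` for a label factor, `"prob"` for the n x 6
#'   probability matrix.
#' @param ... Unused.
#' @return Factor of labels, or a probability matrix with class columns.
#' @export
predict.har_lstm <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  cube <- features_to_cube(newdata, object$input_scale)
  if (dim(cube)[2] != object$config$input_channels) {
    stop("feature channel count does not match the fitted model",
         call. = FALSE)
  }
  probs <- lstm_forward_probs(cube, object$params)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  prob_to_label(probs, object$classes)
}

#' Argmax labels from a probability matrix
#'
#' Ties resolve to the lowest class index (canonical order).
#'
#' @param probs Numeric matrix, one row per window, one column per class.
#' @param classes Class names in canonical order.
#' @return Factor over `classes`.
#' @export
prob_to_label <- function(probs, classes = activity_levels()) {
  idx <- max.col(probs, ties.method = "first")
  factor(classes[idx], levels = classes)
}

#' Evaluate a classifier into a confusion matrix
#'
#' Rows are the model's predictions, columns the actual categories.
#'
#' @param model A fitted [har_lstm()].
#' @param features Test `feature_set` or array.
#' @param labels True labels; taken from the `feature_set` if omitted.
#' @return A `confusion_matrix`: 6 x 6 integer table (rows = predicted,
#'   columns = actual) with the overall accuracy attached.
#' @export
evaluate_classifier <- function(model, features, labels = NULL) {
  y <- feature_labels(features, labels)
  if (length(y) == 0L) stop("test set is empty", call. = FALSE)
  pred <- predict(model, features)
  cm <- table(predicted = pred, actual = y)
  cm <- unclass(cm)[activity_levels(), activity_levels()]
  structure(cm, class = c("confusion_matrix", "matrix"),
            accuracy = sum(diag(cm)) / sum(cm))
}

#' Overall accuracy of a confusion matrix
#' @param cm A `confusion_matrix`.
#' @return Fraction correct (trace over total).
#' @export
accuracy <- function(cm) {
  if (inherits(cm, "confusion_matrix")) return(attr(cm, "accuracy"))
  sum(diag(cm)) / sum(cm)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = actual)\n")
  print(unclass(x)[, , drop = FALSE])
  cat(sprintf("accuracy: %.1f%%\n", 100 * attr(x, "accuracy")))
  invisible(x)
}

# Concatenate feature sets (same width/bins) into one.
combine_features <- function(sets) {
  spectra <- do.call(abind3, lapply(sets, `[[`, "spectra"))
  labels <- do.call(c, lapply(sets, function(s) as.character(s$labels)))
  structure(
    list(spectra = spectra, bin_hz = sets[[1]]$bin_hz,
         width = sets[[1]]$width,
         labels = as_activity_factor(labels),
         start_index = do.call(c, lapply(sets, `[[`, "start_index")),
         subject_id = do.call(c, lapply(sets, function(s)
           rep(s$subject_id[1], nrow(s$spectra))))),
    class = "feature_set"
  )
}

# rbind for 3-d arrays along the first margin
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, dim = c(sum(vapply(parts, function(p) dim(p)[1],
                                            0)), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    if (dim(p)[1] > 0L) out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the fold's subject supplies the test windows and
#' all remaining subjects the training windows, so every fold measures
#' generalisation to an unseen person. Fold seeds derive deterministically
#' from `config$seed` and the held-out subject id.
#'
#' @param subject_features Named list (one element per subject) of labelled
#'   `feature_set`s, e.g. `lapply(simulate_cohort(...), preprocess_labeled)`.
#' @param config An [lstm_config()].
#' @return A `loso_result`: per-subject accuracies, their arithmetic mean,
#'   and per-fold confusion matrices.
#' @export
loso_cv <- function(subject_features, config = lstm_config()) {
  if (length(subject_features) < 2L) {
    stop("leave-one-subject-out requires at least 2 subjects", call. = FALSE)
  }
  ids <- names(subject_features)
  if (is.null(ids)) ids <- paste0("S", seq_along(subject_features))
  accs <- numeric(length(ids))
  cms <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    train_set <- combine_features(subject_features[-i])
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, paste0("fold_", ids[i]))
    model <- har_lstm(train_set, config = fold_cfg)
    cms[[i]] <- evaluate_classifier(model, subject_features[[i]])
    accs[i] <- accuracy(cms[[i]])
  }
  names(accs) <- names(cms) <- ids
  structure(
    list(fold_accuracy = accs, mean_accuracy = mean(accs),
         confusion = cms, config = config),
    class = "loso_result"
  )
}

#' @export
print.loso_result <- function(x, ...) {
  cat("Leave-one-subject-out cross-validation\n")
  for (id in names(x$fold_accuracy)) {
    cat(sprintf("  %s: %.1f%%\n", id, 100 * x$fold_accuracy[id]))
  }
  cat(sprintf("  mean: %.1f%%\n", 100 * x$mean_accuracy))
  invisible(x)
}
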