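# Windowed spectral preprocessing: stream -> fixed-width slices ->
# per-window gravity correction (mean removal) -> one-sided DFT magnitudes.
# All functions are deterministic; window indices are 0-based and windows
# are half-open [start, start + width).

#' Resample a stream to a lower rate
#'
#' Linear interpolation onto a uniform grid at `target_rate`, anchored at the
#' stream's first timestamp. A stream already at the target rate passes
#' through unchanged; upsampling is refused.
#'
#' @param stream An [accel_stream()].
#' @param target_rate Target sampling rate in Hz (default 10, the working
#'   rate of the classifier pipeline).
#' @return An `accel_stream` at `target_rate` with
#'   `round(n * target_rate / rate)` samples.
#' @export
resample_stream <- function(stream, target_rate = 10) {
  if (!inherits(stream, "accel_stream")) {
    stop("stream must be an accel_stream", call. = FALSE)
  }
  stopifnot_scalar_pos(target_rate, "target_rate")
  if (target_rate > stream$rate + 1e-9) {
    stop("upsampling not supported: stream rate ", stream$rate,
         " < target rate ", target_rate, call. = FALSE)
  }
  if (abs(target_rate - stream$rate) < 1e-9) return(stream)
  n_out <- round(n_samples(stream) * target_rate / stream$rate)
  t_out <- stream$t[1] + (seq_len(n_out) - 1) / target_rate
  t_out <- pmin(t_out, max(stream$t))  # guard FP overshoot at the last point
  interp <- function(y) stats::approx(stream$t, y, xout = t_out)$y
  accel_stream(t_out, interp(stream$ax), interp(stream$ay),
               interp(stream$az), target_rate)
}

#' Slice a stream into fixed-width overlapping windows
#'
#' Cuts the stream into windows of `width` samples advancing by
#' `hop = round(width * (1 - overlap))` samples, producing
#' `floor((N - width)/hop) + 1` windows in stream order. When per-sample
#' labels are supplied each window is tagged with its majority label; ties go
#' to the label of the window's first sample.
#'
#' @param stream An [accel_stream()].
#' @param width Window width in samples (default 20, i.e. 2 s at 10 Hz).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param labels Optional per-sample label vector (length = sample count).
#' @param subject_id Optional subject identifier carried through.
#' @return A `window_set`: list with `values` (array n_windows x width x 3,
#'   axes ordered x, y, z), `start_index` (0-based), `width`, `rate`,
#'   `labels` (factor or NULL) and `subject_id`. A stream shorter than
#'   `width` yields an empty set (zero windows) with a warning.
#' @export
slice_windows <- function(stream, width = 20, overlap = 0.5, labels = NULL,
                          subject_id = NA_character_) {
  if (!inherits(stream, "accel_stream")) {
    stop("stream must be an accel_stream", call. = FALSE)
  }
  if (width < 1L) stop("width must be >= 1", call. = FALSE)
  if (overlap < 0 || overlap >= 1) {
    stop("overlap must lie in [0, 1)", call. = FALSE)
  }
  hop <- round(width * (1 - overlap))
  if (hop < 1L) stop("hop = round(width * (1 - overlap)) must be >= 1",
                     call. = FALSE)
  n <- n_samples(stream)
  if (!is.null(labels)) {
    if (length(labels) != n) {
      stop("labels must have one entry per sample", call. = FALSE)
    }
    labels <- as_activity_factor(labels)
  }
  if (n < width) {
    warning("stream shorter than one window; returning empty window set")
    return(empty_window_set(width, stream$rate, subject_id,
                            labelled = !is.null(labels)))
  }
  n_win <- floor((n - width) / hop) + 1
  starts <- (seq_len(n_win) - 1L) * hop           # 0-based
  values <- array(NA_real_, dim = c(n_win, width, 3L),
                  dimnames = list(NULL, NULL, c("x", "y", "z")))
  axes <- cbind(stream$ax, stream$ay, stream$az)
  win_labels <- if (is.null(labels)) NULL else character(n_win)
  for (i in seq_len(n_win)) {
    idx <- (starts[i] + 1L):(starts[i] + width)
    values[i, , ] <- axes[idx, ]
    if (!is.null(labels)) {
      win <- labels[idx]
      tab <- table(win)
      top <- names(tab)[tab == max(tab)]
      win_labels[i] <- if (length(top) == 1L) top else as.character(win[1])
    }
  }
  structure(
    list(values = values, start_index = starts, width = width,
         rate = stream$rate,
         labels = if (is.null(labels)) NULL else as_activity_factor(win_labels),
         subject_id = subject_id),
    class = "window_set"
  )
}

empty_window_set <- function(width, rate, subject_id, labelled = FALSE) {
  structure(
    list(values = array(numeric(0), dim = c(0L, width, 3L)),
         start_index = integer(0), width = width, rate = rate,
         labels = if (labelled) as_activity_factor(character(0)) else NULL,
         subject_id = subject_id),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples x 3 axes @ %g Hz\n",
              nrow(x$values), x$width, x$rate))
  invisible(x)
}

#' Gravity-correct windows by per-axis mean removal
#'
#' Subtracts each window's per-axis mean, removing the quasi-constant
#' gravitational component (and any slow offset) so the spectra's DC bin
#' vanishes. Idempotent.
#'
#' @param windows A `window_set` from [slice_windows()].
#' @return The same `window_set` with zero-mean columns per window and axis.
#' @export
gravity_correct <- function(windows) {
  if (!inherits(windows, "window_set")) {
    stop("windows must be a window_set", call. = FALSE)
  }
  v <- windows$values
  if (nrow(v) > 0L) {
    for (a in 1:3) {
      m <- rowMeans(v[, , a, drop = FALSE])
      v[, , a] <- v[, , a] - m
    }
  }
  windows$values <- v
  windows
}

#' One-sided magnitude spectra of windows
#'
#' Applies [gravity_correct()] and then, per window and axis, takes the
#' magnitudes of the one-sided discrete Fourier transform (rectangular
#' window, no taper): bins `0 .. width/2`, i.e. 11 bins of 0.5 Hz for a
#' 20-sample window at 10 Hz. Parseval's identity holds against the
#' two-sided spectrum: `sum(x^2) = (1/width) * sum(|X_k|^2)`.
#'
#' @param windows A `window_set`.
#' @return A `feature_set`: list with `spectra` (array n_windows x n_bins x
#'   3 of non-negative magnitudes), `bin_hz` (bin width, Hz), `labels`,
#'   `start_index`, `subject_id`.
#' @export
spectral_features <- function(windows) {
  if (!inherits(windows, "window_set")) {
    stop("windows must be a window_set", call. = FALSE)
  }
  windows <- gravity_correct(windows)
  width <- windows$width
  n_bins <- floor(width / 2) + 1L
  n_win <- nrow(windows$values)
  spectra <- array(0, dim = c(n_win, n_bins, 3L),
                   dimnames = list(NULL, NULL, c("x", "y", "z")))
  if (n_win > 0L) {
    for (a in 1:3) {
      # mvfft over columns: one column per window
      M <- matrix(windows$values[, , a], nrow = n_win, ncol = width)
      X <- stats::mvfft(t(M))
      spectra[, , a] <- t(Mod(X[seq_len(n_bins), , drop = FALSE]))
    }
  }
  structure(
    list(spectra = spectra, bin_hz = windows$rate / width,
         width = width, labels = windows$labels,
         start_index = windows$start_index,
         subject_id = windows$subject_id),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d windows, %d bins x 3 axes (bin %g Hz)\n",
              nrow(x$spectra), ncol(x$spectra), x$bin_hz))
  invisible(x)
}

#' Full preprocessing pipeline
#'
#' `resample -> slice -> gravity-correct -> spectra`, the exact feature
#' preparation consumed by the classifier.
#'
#' @param stream An [accel_stream()].
#' @param target_rate Working rate in Hz (default 10).
#' @param width,overlap Window parameters (defaults 20 samples, 50%).
#' @param labels Optional per-sample labels (at the *original* rate; they are
#'   carried through resampling by nearest-neighbour index mapping).
#' @param subject_id Optional subject identifier.
#' @return A `feature_set`.
#' @export
preprocess_stream <- function(stream, target_rate = 10, width = 20,
                              overlap = 0.5, labels = NULL,
                              subject_id = NA_character_) {
  if (!is.null(labels) && length(labels) != n_samples(stream)) {
    stop("labels must have one entry per sample", call. = FALSE)
  }
  rs <- resample_stream(stream, target_rate)
  if (!is.null(labels) && n_samples(rs) != n_samples(stream)) {
    # map each resampled timestamp to the nearest original sample's label
    idx <- pmin(pmax(round((rs$t - stream$t[1]) * stream$rate) + 1L, 1L),
                n_samples(stream))
    labels <- labels[idx]
  }
  spectral_features(
    slice_windows(rs, width = width, overlap = overlap, labels = labels,
                  subject_id = subject_id))
}

#' Preprocess a labelled stream
#'
#' Convenience wrapper applying [preprocess_stream()] to a `labeled_stream`
#' from [simulate_training_session()].
#'
#' @param ls A `labeled_stream`.
#' @param ... Passed to [preprocess_stream()].
#' @return A `feature_set` with window labels and the subject id.
#' @export
preprocess_labeled <- function(ls, ...) {
  preprocess_stream(ls$stream, labels = ls$labels,
                    subject_id = ls$subject_id, ...)
}

#' Flatten a feature set to a table
#'
#' One row per window: subject, 0-based start index, label (if any) and the
#' per-axis magnitude bins as columns `x_bin0 ... z_bin10`.
#'
#' @param features A `feature_set`.
#' @return A data.frame.
#' @export
feature_table <- function(features) {
  n <- nrow(features$spectra)
  n_bins <- ncol(features$spectra)
  mat <- matrix(features$spectra, nrow = n)
  colnames(mat) <- as.vector(outer(paste0("bin", seq_len(n_bins) - 1L),
                                   c("x", "y", "z"),
                                   function(b, a) paste(a, b, sep = "_")))
  df <- data.frame(subject = rep(features$subject_id, n),
                   start_index = features$start_index,
                   label = if (is.null(features$labels)) NA_character_
                           else as.character(features$labels),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(mat))
}
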