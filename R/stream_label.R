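# Apply a trained classifier to long unlabeled recordings and summarise
# per-category window counts (the movement-count profile of a session).

#' Label a long recording and count movement windows
#'
#' Runs the full inference pipeline (resample to the working rate, slice
#' into overlapping windows, gravity-correct, Fourier-transform, predict)
#' and returns per-category window counts together with the per-window
#' label track aligned to window start times. No smoothing is applied to
#' the label track by default; an optional odd-width majority-vote smoother
#' is available.
#'
#' @param model A fitted [har_lstm()].
#' @param stream An [accel_stream()] recording.
#' @param target_rate Working rate in Hz (default 10).
#' @param width,overlap Window parameters (defaults 20 samples, 50%).
#' @param smooth Odd integer width of a majority-vote smoother applied to
#'   the label track, or `NULL` (default) for raw labels.
#' @return An `activity_counts`: list with `counts` (named integer vector
#'   over [activity_levels()]), `total`, `duration` (s), and `track`
#'   (data.frame of window start time and label). A stream too short for a
#'   single window yields zero counts with a warning.
#' @export
label_stream <- function(model, stream, target_rate = 10, width = 20,
                         overlap = 0.5, smooth = NULL) {
  if (!inherits(model, "har_lstm")) stop("model must be a har_lstm",
                                         call. = FALSE)
  duration <- n_samples(stream) / stream$rate
  feats <- suppressWarnings(
    preprocess_stream(stream, target_rate = target_rate, width = width,
                      overlap = overlap))
  if (nrow(feats$spectra) == 0L) {
    warning("recording shorter than one window; returning empty counts")
    counts <- stats::setNames(integer(length(activity_levels())),
                              activity_levels())
    return(structure(list(counts = counts, total = 0L, duration = duration,
                          track = data.frame(time = numeric(0),
                                             label = character(0))),
                     class = "activity_counts"))
  }
  labels <- predict(model, feats)
  if (!is.null(smooth)) labels <- majority_smooth(labels, smooth)
  counts <- table(labels)
  counts <- stats::setNames(as.integer(counts[activity_levels()]),
                            activity_levels())
  track <- data.frame(time = feats$start_index / target_rate,
                      label = as.character(labels),
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, total = length(labels),
                 duration = duration, track = track),
            class = "activity_counts")
}

# Odd-width sliding majority vote over a label factor; ties keep the
# centre label.
majority_smooth <- function(labels, width) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) {
    stop("smooth width must be a positive odd integer", call. = FALSE)
  }
  if (width == 1L || length(labels) == 0L) return(labels)
  half <- width %/% 2L
  out <- labels
  n <- length(labels)
  for (i in seq_len(n)) {
    win <- labels[max(1L, i - half):min(n, i + half)]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (as.character(labels[i]) %in% top) as.character(labels[i])
              else top[1]
  }
  out
}

#' @export
print.activity_counts <- function(x, ...) {
  cat(sprintf("Movement window counts over %.1f min (%d windows)\n",
              x$duration / 60, x$total))
  print(x$counts)
  invisible(x)
}

#' Write activity counts as CSV
#'
#' One row: the six canonical label counts plus the total.
#'
#' @param counts An `activity_counts`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_activity_counts <- function(counts, path) {
  df <- as.data.frame(as.list(counts$counts))
  df$total <- counts$total
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
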