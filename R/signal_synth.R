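# Synthetic triaxial accelerometer streams for the six instructed chest
# movements. The device frame follows the chest-worn convention: the phone
# sits flat at the centre of the clavicle, so z carries gravity when seated
# upright, x is lateral (side-to-side sway) and y is anterior-posterior
# (back-and-forth rocking).

#' Construct a triaxial accelerometer stream
#'
#' A light container for a fixed-rate triaxial acceleration record:
#' strictly increasing timestamps with spacing `1/rate` and three equal-length
#' axis series in m/s^2.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing,
#'   uniformly spaced at `1/rate`.
#' @param ax,ay,az Numeric acceleration series (m/s^2), same length as `t`.
#' @param rate Sampling rate in Hz (> 0).
#' @return An object of class `accel_stream`: a list with elements
#'   `rate`, `t`, `ax`, `ay`, `az`.
#' @export
accel_stream <- function(t, ax, ay, az, rate) {
  stopifnot_scalar_pos(rate, "rate")
  n <- length(t)
  if (n < 1L) stop("stream must contain at least one sample", call. = FALSE)
  if (length(ax) != n || length(ay) != n || length(az) != n) {
    stop("t, ax, ay, az must have equal length", call. = FALSE)
  }
  if (n > 1L) {
    d <- diff(t)
    if (any(d <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
    if (max(abs(d - 1 / rate)) > 1e-6 / rate + 1e-9) {
      stop("timestamp spacing must equal 1/rate", call. = FALSE)
    }
  }
  structure(
    list(rate = rate, t = as.numeric(t), ax = as.numeric(ax),
         ay = as.numeric(ay), az = as.numeric(az)),
    class = "accel_stream"
  )
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> %d samples @ %g Hz (%.1f s)\n",
              length(x$t), x$rate, length(x$t) / x$rate))
  invisible(x)
}

#' Number of samples in a stream
#' @param stream An `accel_stream`.
#' @return Integer sample count.
#' @export
n_samples <- function(stream) length(stream$t)

#' Motion model parameters for the six movement classes
#'
#' Per-class signal models used by [simulate_activity()]. Each oscillatory
#' class is a sinusoid on its designated axis/axes; `stand_sit` is a train of
#' alternating-sign vertical Gaussian pulses; `still` is gravity plus noise
#' only. Defaults keep every oscillation well below the 5 Hz Nyquist limit of
#' a 10 Hz recording and within the 2-5 s time span typical of daily seated
#' movements.
#'
#' @param gravity Gravitational acceleration on the z axis (m/s^2).
#' @param noise_sd Standard deviation of white sensor/body noise added to all
#'   axes (m/s^2).
#' @param walk_freq,walk_amp_z,walk_amp_x Stride frequency (Hz), vertical
#'   bounce amplitude and lateral sway amplitude (sway runs at half the
#'   stride frequency).
#' @param rotate_freq,rotate_amp Torso rotation: phase-shifted oscillation of
#'   equal amplitude on both horizontal axes.
#' @param swing_freq,swing_amp Side-to-side sway on the lateral (x) axis.
#' @param rock_freq,rock_amp Back-and-forth rocking on the
#'   anterior-posterior (y) axis.
#' @param standsit_period,standsit_height,standsit_width Stand-up/sit-down
#'   transients: one vertical Gaussian pulse (alternating sign) every
#'   `standsit_period` seconds, of the given height (m/s^2) and width
#'   (Gaussian sigma, seconds).
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(gravity = 9.81,
                          noise_sd = 0.3,
                          walk_freq = 2.0, walk_amp_z = 3.0, walk_amp_x = 1.0,
                          rotate_freq = 0.5, rotate_amp = 1.5,
                          swing_freq = 0.6, swing_amp = 2.0,
                          rock_freq = 0.6, rock_amp = 2.0,
                          standsit_period = 2.5, standsit_height = 4.0,
                          standsit_width = 0.3) {
  p <- list(gravity = gravity, noise_sd = noise_sd,
            walk_freq = walk_freq, walk_amp_z = walk_amp_z,
            walk_amp_x = walk_amp_x,
            rotate_freq = rotate_freq, rotate_amp = rotate_amp,
            swing_freq = swing_freq, swing_amp = swing_amp,
            rock_freq = rock_freq, rock_amp = rock_amp,
            standsit_period = standsit_period,
            standsit_height = standsit_height,
            standsit_width = standsit_width)
  amps <- c(p$walk_amp_z, p$walk_amp_x, p$rotate_amp, p$swing_amp, p$rock_amp,
            p$standsit_height, p$noise_sd)
  if (any(amps < 0)) stop("amplitudes and noise sd must be >= 0", call. = FALSE)
  if (any(c(p$walk_freq, p$rotate_freq, p$swing_freq, p$rock_freq,
            1 / p$standsit_period) <= 0)) {
    stop("class frequencies must be positive", call. = FALSE)
  }
  class(p) <- "motion_params"
  p
}

# Largest oscillation frequency a parameter set generates; used for the
# Nyquist guard.
max_model_freq <- function(params) {
  max(params$walk_freq, params$rotate_freq, params$swing_freq,
      params$rock_freq)
}

#' Simulate one instructed movement
#'
#' Generates a fixed-rate triaxial stream with the class-specific structure:
#' `still` is gravity plus noise only; `swing` a lateral-axis sinusoid;
#' `rock` an anterior-posterior sinusoid; `rotate` a quarter-period
#' phase-shifted oscillation on both horizontal axes; `walk` a vertical
#' bounce at the stride frequency plus a lateral sway at half that
#' frequency; `stand_sit` repeated alternating vertical transients on top of
#' gravity. Oscillation phases and the noise are drawn from the seeded RNG,
#' so identical `(label, duration, rate, params, seed)` give identical
#' streams.
#'
#' @param label One of [activity_levels()].
#' @param duration Recording length in seconds (> 0).
#' @param rate Sampling rate in Hz (> 0); oscillation frequencies in
#'   `params` must stay below `rate/2`.
#' @param params A [motion_params()] object.
#' @param seed Integer RNG seed.
#' @return An [accel_stream()] of `round(duration * rate)` samples.
#' @examples
#' s <- simulate_activity("swing", duration = 10, rate = 10, seed = 1)
#' n_samples(s)
#' @export
simulate_activity <- function(label, duration, rate = 10,
                              params = motion_params(), seed = 1L) {
  label <- match.arg(label, activity_levels())
  stopifnot_scalar_pos(duration, "duration")
  stopifnot_scalar_pos(rate, "rate")
  if (max_model_freq(params) >= rate / 2) {
    stop("oscillation frequency >= Nyquist limit (rate/2)", call. = FALSE)
  }
  n <- round(duration * rate)
  if (n < 1L) stop("duration too short for one sample at this rate",
                   call. = FALSE)
  t <- (seq_len(n) - 1) / rate
  with_seed(seed, {
    ax <- ay <- az <- numeric(n)
    two_pi <- 2 * pi
    phase <- function() runif(1, 0, two_pi)
    switch(label,
      still = NULL,
      swing = {
        ax <- params$swing_amp * sin(two_pi * params$swing_freq * t + phase())
      },
      rock = {
        ay <- params$rock_amp * sin(two_pi * params$rock_freq * t + phase())
      },
      rotate = {
        ph <- phase()
        ax <- params$rotate_amp * sin(two_pi * params$rotate_freq * t + ph)
        ay <- params$rotate_amp * sin(two_pi * params$rotate_freq * t + ph + pi / 2)
      },
      walk = {
        az <- params$walk_amp_z * sin(two_pi * params$walk_freq * t + phase())
        ax <- params$walk_amp_x * sin(two_pi * (params$walk_freq / 2) * t + phase())
      },
      stand_sit = {
        offset <- runif(1, 0.5, min(1.5, params$standsit_period))
        centres <- seq(offset, max(t), by = params$standsit_period)
        sgn <- rep_len(c(1, -1), length(centres))
        for (k in seq_along(centres)) {
          az <- az + sgn[k] * params$standsit_height *
            exp(-(t - centres[k])^2 / (2 * params$standsit_width^2))
        }
      }
    )
    az <- az + params$gravity
    if (params$noise_sd > 0) {
      ax <- ax + rnorm(n, 0, params$noise_sd)
      ay <- ay + rnorm(n, 0, params$noise_sd)
      az <- az + rnorm(n, 0, params$noise_sd)
    }
    accel_stream(t, ax, ay, az, rate)
  })
}

#' Default training-session script
#'
#' The instructed session: each of the six movements held for a fixed
#' duration, in canonical order.
#'
#' @param duration_per_activity Seconds per movement (default 10, the
#'   instructor-counted interval).
#' @return A data.frame with columns `label` and `duration`.
#' @export
default_training_script <- function(duration_per_activity = 10) {
  data.frame(label = activity_levels(),
             duration = duration_per_activity,
             stringsAsFactors = FALSE)
}

# Multiplicative per-subject jitter of motion parameters, drawn from a
# subject-specific seeded stream so leave-one-subject-out folds face genuine
# inter-subject variability.
jitter_params <- function(params, subject_seed, amp_sd = 0.15, freq_sd = 0.10) {
  with_seed(subject_seed, {
    amp_fields <- c("walk_amp_z", "walk_amp_x", "rotate_amp", "swing_amp",
                    "rock_amp", "standsit_height")
    freq_fields <- c("walk_freq", "rotate_freq", "swing_freq", "rock_freq",
                     "standsit_period")
    for (f in amp_fields) params[[f]] <- params[[f]] * exp(rnorm(1, 0, amp_sd))
    for (f in freq_fields) params[[f]] <- params[[f]] * exp(rnorm(1, 0, freq_sd))
    params
  })
}

#' Simulate a labelled training session for one subject
#'
#' Runs an ordered script of (label, duration) segments, concatenating the
#' per-segment streams onto a single continuous time axis and recording the
#' per-sample label. With `jitter = TRUE` (default) the motion parameters are
#' first perturbed multiplicatively by a subject-specific seeded draw, so
#' different subjects move with different amplitudes and tempos.
#'
#' @param subject_id Opaque subject identifier (string).
#' @param script Data.frame with columns `label`, `duration`; defaults to the
#'   six instructed movements at 10 s each.
#' @param rate Sampling rate in Hz.
#' @param params Base [motion_params()].
#' @param seed Integer seed; the subject stream is derived from
#'   `(seed, subject_id)` so cohorts are reproducible subject by subject.
#' @param jitter Apply per-subject parameter jitter?
#' @param jitter_amp_sd,jitter_freq_sd Log-scale SDs of the multiplicative
#'   amplitude and frequency jitter.
#' @return A `labeled_stream`: list with `stream` ([accel_stream()]),
#'   `labels` (per-sample factor over [activity_levels()]) and `subject_id`.
#' @export
simulate_training_session <- function(subject_id,
                                      script = default_training_script(),
                                      rate = 10,
                                      params = motion_params(),
                                      seed = 1L,
                                      jitter = TRUE,
                                      jitter_amp_sd = 0.15,
                                      jitter_freq_sd = 0.10) {
  if (is.null(script) || nrow(script) == 0L) {
    stop("script must contain at least one (label, duration) row",
         call. = FALSE)
  }
  subject_seed <- derive_seed(seed, subject_id)
  if (jitter) {
    params <- jitter_params(params, derive_seed(subject_seed, "jitter"),
                            amp_sd = jitter_amp_sd, freq_sd = jitter_freq_sd)
  }
  segs <- vector("list", nrow(script))
  labs <- vector("list", nrow(script))
  for (i in seq_len(nrow(script))) {
    seg_seed <- derive_seed(subject_seed, paste0("segment", i))
    s <- simulate_activity(script$label[i], script$duration[i], rate = rate,
                           params = params, seed = seg_seed)
    segs[[i]] <- s
    labs[[i]] <- rep(script$label[i], n_samples(s))
  }
  ax <- unlist(lapply(segs, `[[`, "ax"))
  ay <- unlist(lapply(segs, `[[`, "ay"))
  az <- unlist(lapply(segs, `[[`, "az"))
  n <- length(ax)
  stream <- accel_stream((seq_len(n) - 1) / rate, ax, ay, az, rate)
  structure(
    list(stream = stream,
         labels = as_activity_factor(unlist(labs)),
         subject_id = as.character(subject_id)),
    class = "labeled_stream"
  )
}

#' @export
print.labeled_stream <- function(x, ...) {
  cat(sprintf("<labeled_stream> subject %s: %d samples @ %g Hz\n",
              x$subject_id, n_samples(x$stream), x$stream$rate))
  print(table(x$labels))
  invisible(x)
}

#' Simulate a labelled cohort
#'
#' Convenience wrapper generating one [simulate_training_session()] per
#' subject with distinct derived seeds.
#'
#' @param n_subjects Number of subjects.
#' @param duration_per_activity Seconds per movement for every subject.
#' @param rate Sampling rate in Hz.
#' @param params Base [motion_params()].
#' @param seed Integer seed.
#' @param jitter Apply per-subject parameter jitter?
#' @return Named list of `labeled_stream` objects (`S1`, `S2`, ...).
#' @export
simulate_cohort <- function(n_subjects = 5, duration_per_activity = 10,
                            rate = 10, params = motion_params(), seed = 1L,
                            jitter = TRUE) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  ids <- paste0("S", seq_len(n_subjects))
  out <- lapply(ids, function(id) {
    simulate_training_session(
      id, script = default_training_script(duration_per_activity),
      rate = rate, params = params, seed = seed, jitter = jitter)
  })
  names(out) <- ids
  out
}

#' Write / read a sensor log
#'
#' Plain-CSV serialisation of an [accel_stream()], emulating a smartphone
#' app export: header exactly `Timestamp,X,Y,Z`, comma separated, dot
#' decimal, timestamps in seconds from stream start, values written with
#' full double precision (round-trips to well within 1e-6).
#'
#' @param stream An `accel_stream`.
#' @param path File path.
#' @return `write_sensor_log` returns `path` invisibly; `read_sensor_log`
#'   returns an `accel_stream`.
#' @export
write_sensor_log <- function(stream, path) {
  if (!inherits(stream, "accel_stream")) {
    stop("stream must be an accel_stream", call. = FALSE)
  }
  df <- data.frame(Timestamp = stream$t, X = stream$ax, Y = stream$ay,
                   Z = stream$az)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_log
#' @export
read_sensor_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("sensor log is empty: ", path, call. = FALSE)
  }
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("Timestamp", "X", "Y", "Z"))) {
    stop("line 1: expected header 'Timestamp,X,Y,Z', got '", lines[1], "'",
         call. = FALSE)
  }
  if (length(lines) == 1L) {
    stop("sensor log has a header but no samples: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, header = TRUE, colClasses = "numeric")
  if (anyNA(df)) {
    bad <- which(!stats::complete.cases(df))[1]
    stop("line ", bad + 1L, ": non-numeric or missing field", call. = FALSE)
  }
  d <- diff(df$Timestamp)
  if (length(d) > 0 && any(d <= 0)) {
    bad <- which(d <= 0)[1]
    stop("line ", bad + 2L, ": timestamps not strictly increasing",
         call. = FALSE)
  }
  rate <- if (length(d) > 0) 1 / stats::median(d) else 1
  accel_stream(df$Timestamp, df$X, df$Y, df$Z, rate)
}
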