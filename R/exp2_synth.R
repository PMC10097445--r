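# Synthetic Experiment-2 data: subject-level tables with the observed
# descriptive shape (movement counts, shift-trial RT, accuracy, salivary
# alpha-amylase stress) plus configurable planted path effects, and
# trial-level Navon records with a balanced mixed phase.

#' Configuration for the subject-table generator
#'
#' Location/scale defaults are the observed descriptives of the 28-subject
#' study sample (movement window counts over 30 min, shift-trial reaction
#' time in ms, shift accuracy, salivary alpha-amylase stress index). Planted
#' effects default to zero: reaction time is then pure noise around its
#' mean, and the table is a null data set for the mediation machinery.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param movement_means,movement_sds Named location/scale for the six
#'   movement counts (`walking`, `stand_sit`, `rotating`, `swinging`,
#'   `rocking`, `sitting`). Counts are drawn normal, censored at 0 and
#'   rounded to integers.
#' @param rt_intercept,rt_sd Mediator (shift-trial RT, ms): intercept and
#'   residual SD of `rt = rt_intercept + sum(a * movement) + noise`.
#' @param accuracy_intercept,accuracy_sd Accuracy equation intercept and
#'   residual SD; values are clamped to `[0, 1]`.
#' @param stress_intercept,stress_sd Stress equation intercept and residual
#'   SD (not clamped).
#' @param a Named movement -> RT path coefficients (over `swinging`,
#'   `rotating`, `sitting`); default all zero.
#' @param b_accuracy,b_stress RT -> outcome path coefficients.
#' @param direct_accuracy,direct_stress Named direct movement -> outcome
#'   coefficients; default all zero.
#' @param missing_stress_prob Probability that a subject's stress reading
#'   is missing (default 2/28, the observed missingness).
#' @return A list of class `exp2_config`.
#' @export
exp2_config <- function(n_subjects = 28,
                        movement_means = c(walking = 28.143,
                                           stand_sit = 38.214,
                                           rotating = 354.214,
                                           swinging = 44.536,
                                           rocking = 62.464,
                                           sitting = 1082.643),
                        movement_sds = c(walking = 31.053,
                                         stand_sit = 24.745,
                                         rotating = 184.761,
                                         swinging = 21.384,
                                         rocking = 30.827,
                                         sitting = 332.709),
                        rt_intercept = 1468.83, rt_sd = 515.088,
                        accuracy_intercept = 0.968, accuracy_sd = 0.08,
                        stress_intercept = 25.462, stress_sd = 15.103,
                        a = c(swinging = 0, rotating = 0, sitting = 0),
                        b_accuracy = 0, b_stress = 0,
                        direct_accuracy = c(swinging = 0, rotating = 0,
                                            sitting = 0),
                        direct_stress = c(swinging = 0, rotating = 0,
                                          sitting = 0),
                        missing_stress_prob = 2 / 28) {
  if (n_subjects < 4L) stop("n_subjects must be >= 4", call. = FALSE)
  if (any(movement_sds < 0) || rt_sd < 0 || accuracy_sd < 0 ||
      stress_sd < 0) {
    stop("scales must be >= 0", call. = FALSE)
  }
  if (missing_stress_prob < 0 || missing_stress_prob > 1) {
    stop("missing_stress_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         movement_means = movement_means, movement_sds = movement_sds,
         rt_intercept = rt_intercept, rt_sd = rt_sd,
         accuracy_intercept = accuracy_intercept, accuracy_sd = accuracy_sd,
         stress_intercept = stress_intercept, stress_sd = stress_sd,
         a = a, b_accuracy = b_accuracy, b_stress = b_stress,
         direct_accuracy = direct_accuracy, direct_stress = direct_stress,
         missing_stress_prob = missing_stress_prob),
    class = "exp2_config"
  )
}

#' Generate a synthetic subject table
#'
#' Movement counts are drawn normal at the configured location/scale,
#' censored at zero and rounded. The mediator and outcomes follow the
#' linear path model: `rt = rt_intercept + sum(a * X) + noise`,
#' `accuracy = clamp(accuracy_intercept + b_accuracy * rt +
#' sum(direct_accuracy * X) + noise, 0, 1)`, and stress analogously
#' (unclamped). Stress readings are set missing with the configured
#' probability.
#'
#' @param config An [exp2_config()].
#' @param seed Integer seed; identical (config, seed) give identical tables.
#' @return Data.frame with columns `participant`, the six movement counts,
#'   `reaction_time`, `accuracy`, `stress`.
#' @export
generate_exp2_dataset <- function(config = exp2_config(), seed = 1L) {
  if (!inherits(config, "exp2_config")) {
    stop("config must be an exp2_config", call. = FALSE)
  }
  n <- config$n_subjects
  with_seed(seed, {
    counts <- sapply(names(config$movement_means), function(v) {
      pmax(0, round(stats::rnorm(n, config$movement_means[v],
                                 config$movement_sds[v])))
    })
    counts <- as.data.frame(counts)
    pred <- as.matrix(counts[names(config$a)])
    rt <- config$rt_intercept + drop(pred %*% config$a) +
      stats::rnorm(n, 0, config$rt_sd)
    accuracy <- config$accuracy_intercept + config$b_accuracy * rt +
      drop(pred %*% config$direct_accuracy) +
      stats::rnorm(n, 0, config$accuracy_sd)
    accuracy <- pmin(1, pmax(0, accuracy))
    stress <- config$stress_intercept + config$b_stress * rt +
      drop(pred %*% config$direct_stress) +
      stats::rnorm(n, 0, config$stress_sd)
    stress[stats::runif(n) < config$missing_stress_prob] <- NA_real_
    cbind(data.frame(participant = sprintf("P%02d", seq_len(n)),
                     stringsAsFactors = FALSE),
          counts,
          data.frame(reaction_time = rt, accuracy = accuracy,
                     stress = stress))
  })
}

#' Configuration for the trial-level Navon generator
#'
#' Condition reaction-time locations/scales default to the observed
#' condition means and SDs (global, local, nonshift, shift; ms). Each
#' subject receives a shared random shift (`subject_sd`) plus a
#' condition-specific deviation sized so the between-subject SD of each
#' condition mean matches `condition_sds`; individual trials are then
#' lognormal around the subject-condition mean with coefficient of
#' variation `within_cv`. The mixed phase is constructed with shift and
#' nonshift transitions balanced to within one trial, randomly ordered.
#'
#' @param n_subjects Number of subjects.
#' @param condition_means,condition_sds Named (global, local, nonshift,
#'   shift) RT means and between-subject SDs in ms.
#' @param subject_sd SD of the shared (condition-independent) subject
#'   effect, ms. Must not exceed any condition SD.
#' @param within_cv Within-subject trial-level coefficient of variation.
#' @param p_correct Per-trial probability of a correct response.
#' @param n_single Trials in each of the global and local phases.
#' @param n_mixed Trials in the mixed phase.
#' @return A list of class `navon_trial_config`.
#' @export
navon_trial_config <- function(n_subjects = 28,
                               condition_means = c(global = 932.83,
                                                   local = 1101.13,
                                                   nonshift = 1345.168,
                                                   shift = 1468.83),
                               condition_sds = c(global = 217.05,
                                                 local = 302.79,
                                                 nonshift = 430.02,
                                                 shift = 515.09),
                               subject_sd = 200,
                               within_cv = 0.2,
                               p_correct = 0.968,
                               n_single = 20, n_mixed = 40) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (any(condition_sds < subject_sd)) {
    stop("subject_sd must not exceed any condition SD", call. = FALSE)
  }
  if (p_correct <= 0 || p_correct > 1) {
    stop("p_correct must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         condition_means = condition_means, condition_sds = condition_sds,
         subject_sd = subject_sd, within_cv = within_cv,
         p_correct = p_correct, n_single = as.integer(n_single),
         n_mixed = as.integer(n_mixed)),
    class = "navon_trial_config"
  )
}

# A mixed-phase kind sequence whose shift/nonshift transition counts differ
# by at most one, in random order.
mixed_kind_sequence <- function(n_mixed) {
  n_trans <- n_mixed - 1L
  n_shift <- n_trans %/% 2L + sample(0:1, 1) * (n_trans %% 2L)
  trans <- sample(c(rep(TRUE, n_shift), rep(FALSE, n_trans - n_shift)))
  kinds <- character(n_mixed)
  kinds[1] <- sample(c("global", "local"), 1)
  for (i in seq_len(n_trans)) {
    kinds[i + 1] <- if (trans[i]) setdiff(c("global", "local"), kinds[i])
                    else kinds[i]
  }
  kinds
}

#' Generate trial-level Navon records
#'
#' Per subject: `n_single` global-phase trials, `n_single` local-phase
#' trials, and `n_mixed` mixed-phase trials with balanced, randomly ordered
#' shift/nonshift transitions. RTs are lognormal around the
#' subject-condition mean (see [navon_trial_config()]); correctness is
#' Bernoulli.
#'
#' @param config A [navon_trial_config()].
#' @param seed Integer seed.
#' @return Data.frame with columns `participant`, `phase`, `trial_kind`,
#'   `rt`, `correct`, `trial` — the input format of
#'   [condition_summaries()].
#' @export
generate_trials <- function(config = navon_trial_config(), seed = 1L) {
  if (!inherits(config, "navon_trial_config")) {
    stop("config must be a navon_trial_config", call. = FALSE)
  }
  cm <- config$condition_means
  cond_dev_sd <- sqrt(pmax(config$condition_sds^2 - config$subject_sd^2, 0))
  sig2 <- log(1 + config$within_cv^2)
  draw_rt <- function(mu, n) {
    mu <- pmax(mu, 100)  # keep subject-condition means physically plausible
    stats::rlnorm(n, meanlog = log(mu) - sig2 / 2, sdlog = sqrt(sig2))
  }
  with_seed(seed, {
    rows <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      u <- stats::rnorm(1, 0, config$subject_sd)
      mu <- cm + u + stats::rnorm(length(cm), 0, cond_dev_sd)
      names(mu) <- names(cm)
      n1 <- config$n_single
      kinds <- mixed_kind_sequence(config$n_mixed)
      tags <- as.character(tag_shift_trials(kinds))
      cond_mixed <- ifelse(tags == "shift", "shift", "nonshift")
      rts <- c(draw_rt(mu["global"], n1), draw_rt(mu["local"], n1),
               vapply(cond_mixed, function(cc) draw_rt(mu[cc], 1), 0))
      rows[[s]] <- data.frame(
        participant = sprintf("P%02d", s),
        phase = c(rep("global", n1), rep("local", n1),
                  rep("mixed", config$n_mixed)),
        trial_kind = c(rep("global", n1), rep("local", n1), kinds),
        rt = rts,
        correct = stats::runif(2 * n1 + config$n_mixed) <= config$p_correct,
        trial = c(seq_len(n1), seq_len(n1), seq_len(config$n_mixed)),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
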