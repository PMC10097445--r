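# Bootstrap mediation: movement counts -> shift-trial reaction time ->
# accuracy / stress. One mediator equation (RT on the three movement
# predictors jointly) and one outcome equation per outcome (outcome on RT
# plus the predictors). Indirect effect = a * b; total = direct + indirect
# (an exact identity of the linear path model). Point estimates are OLS
# (equal to ML under normal errors); uncertainty comes from delta-method
# standard errors and bias-corrected percentile bootstrap CIs over case
# resampling.

# Small dense OLS with standard errors; returns NULL on a singular design.
ols_fit <- function(X, y) {
  XtX <- crossprod(X)
  XtXinv <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(XtXinv) || nrow(X) <= ncol(X)) return(NULL)
  coef <- drop(XtXinv %*% crossprod(X, y))
  res <- y - drop(X %*% coef)
  rss <- sum(res^2)
  sigma2 <- rss / (nrow(X) - ncol(X))
  tss <- sum((y - mean(y))^2)
  list(coef = coef, se = sqrt(pmax(diag(XtXinv) * sigma2, 0)),
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
}

# Fit all path equations on one data set. Returns NULL if any equation is
# singular or an outcome has too few complete rows.
fit_path_model <- function(data, predictors, mediator, outcomes) {
  Xm <- cbind(1, as.matrix(data[predictors]))
  med <- ols_fit(Xm, data[[mediator]])
  if (is.null(med)) return(NULL)
  a <- med$coef[-1]; se_a <- med$se[-1]
  names(a) <- names(se_a) <- predictors
  out_eq <- list()
  for (yv in outcomes) {
    ok <- !is.na(data[[yv]])
    if (sum(ok) < length(predictors) + 3L) return(NULL)
    d <- data[ok, , drop = FALSE]
    Xo <- cbind(1, as.matrix(d[mediator]), as.matrix(d[predictors]))
    fit <- ols_fit(Xo, d[[yv]])
    if (is.null(fit)) return(NULL)
    # reduced form (outcome on predictors only) supplies the total-effect SE
    red <- ols_fit(cbind(1, as.matrix(d[predictors])), d[[yv]])
    if (is.null(red)) return(NULL)
    b <- fit$coef[2]; se_b <- fit$se[2]
    cprime <- fit$coef[-(1:2)]; se_c <- fit$se[-(1:2)]
    names(cprime) <- names(se_c) <- predictors
    out_eq[[yv]] <- list(
      b = b, se_b = se_b, direct = cprime, se_direct = se_c,
      se_total = stats::setNames(red$se[-1], predictors),
      r_squared = fit$r_squared, n = sum(ok))
  }
  list(a = a, se_a = se_a, r_squared_mediator = med$r_squared,
       outcomes = out_eq)
}

# Flatten a fitted path model into the named estimate vector used by the
# bootstrap: direct/indirect/total per (predictor, outcome).
path_estimates <- function(fit, predictors, outcomes) {
  est <- c()
  for (yv in outcomes) {
    eq <- fit$outcomes[[yv]]
    for (xv in predictors) {
      ind <- fit$a[xv] * eq$b
      est[paste("direct", xv, yv, sep = ".")] <- eq$direct[xv]
      est[paste("indirect", xv, yv, sep = ".")] <- ind
      est[paste("total", xv, yv, sep = ".")] <- eq$direct[xv] + ind
    }
  }
  est
}

# Bias-corrected percentile interval.
bc_ci <- function(boot, est, conf) {
  boot <- boot[is.finite(boot)]
  nb <- length(boot)
  if (nb < 20L) return(c(NA_real_, NA_real_))
  prop <- mean(boot < est)
  prop <- min(max(prop, 1 / (2 * nb)), 1 - 1 / (2 * nb))
  z0 <- stats::qnorm(prop)
  alpha <- (1 - conf) / 2
  qs <- stats::pnorm(2 * z0 + stats::qnorm(c(alpha, 1 - alpha)))
  unname(stats::quantile(boot, qs, names = FALSE))
}

#' Bootstrap mediation of movement effects through reaction time
#'
#' Fits the path model in which shift-trial reaction time mediates the
#' effect of movement counts on each outcome: one mediator equation
#' (`mediator ~ predictors`, all predictors jointly) and per outcome
#' `outcome ~ mediator + predictors`. For each (predictor, outcome) pair
#' the indirect effect is `a * b`, the direct effect the predictor's
#' coefficient in the outcome equation, and the total their sum (exact for
#' the OLS point estimates). Rows missing an outcome (e.g. unavailable
#' stress readings) are excluded from that outcome's equations only.
#'
#' Standard errors are delta-method (Sobel for the indirect path); 95%
#' intervals are bias-corrected percentile bootstrap over case resampling.
#' Resamples with a singular fit are skipped and the achieved resample
#' count is reported. Standardised estimates refit the model on z-scored
#' variables.
#'
#' @param data Data.frame containing the predictor, mediator and outcome
#'   columns. At least 10 complete rows are required (stress may be
#'   missing).
#' @param predictors Movement-count column names (default `swinging`,
#'   `rotating`, `sitting`).
#' @param mediator Mediator column (default `reaction_time`).
#' @param outcomes Outcome columns (default `accuracy`, `stress`).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed; identical seeds give identical CIs.
#' @return A `mediation_fit`: `paths` data.frame (predictor, outcome,
#'   effect, estimate, se, z, p, ci_lower, ci_upper, std_estimate),
#'   `r_squared` per equation, `a_paths`, `b_paths`, `n`, `n_boot`,
#'   `n_boot_achieved`.
#' @export
mediate_boot <- function(data,
                         predictors = c("swinging", "rotating", "sitting"),
                         mediator = "reaction_time",
                         outcomes = c("accuracy", "stress"),
                         n_boot = 2000, conf = 0.95, seed = 1L) {
  vars <- c(predictors, mediator, outcomes)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  core <- c(predictors, mediator)
  data <- data[stats::complete.cases(data[core]), vars, drop = FALSE]
  n <- nrow(data)
  if (n < 10L) stop("need at least 10 complete rows", call. = FALSE)

  fit <- fit_path_model(data, predictors, mediator, outcomes)
  if (is.null(fit)) stop("singular design on the full data", call. = FALSE)
  est <- path_estimates(fit, predictors, outcomes)

  # standardised point estimates (z-scored variables, per-column scaling)
  zdata <- data
  for (v in vars) {
    x <- zdata[[v]]
    zdata[[v]] <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  }
  zfit <- fit_path_model(zdata, predictors, mediator, outcomes)
  zest <- if (is.null(zfit)) est * NA else path_estimates(zfit, predictors,
                                                          outcomes)

  boot <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  achieved <- 0L
  with_seed(seed, {
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      bfit <- fit_path_model(data[idx, , drop = FALSE], predictors,
                             mediator, outcomes)
      if (is.null(bfit)) next
      achieved <- achieved + 1L
      boot[bi, ] <- path_estimates(bfit, predictors, outcomes)
    }
  })

  rows <- list()
  for (yv in outcomes) {
    eq <- fit$outcomes[[yv]]
    for (xv in predictors) {
      se_dir <- eq$se_direct[xv]
      se_ind <- sqrt(fit$a[xv]^2 * eq$se_b^2 + eq$b^2 * fit$se_a[xv]^2)
      se_tot <- eq$se_total[xv]
      for (eff in c("direct", "indirect", "total")) {
        nm <- paste(eff, xv, yv, sep = ".")
        se <- switch(eff, direct = se_dir, indirect = se_ind,
                     total = se_tot)
        ci <- bc_ci(boot[, nm], est[nm], conf)
        z <- est[nm] / se
        rows[[nm]] <- data.frame(
          predictor = xv, outcome = yv, effect = eff,
          estimate = unname(est[nm]), se = unname(se), z = unname(z),
          p = unname(2 * stats::pnorm(-abs(z))),
          ci_lower = ci[1], ci_upper = ci[2],
          std_estimate = unname(zest[nm]), stringsAsFactors = FALSE)
      }
    }
  }
  paths <- do.call(rbind, rows)
  rownames(paths) <- NULL

  r2 <- c(mediator = fit$r_squared_mediator,
          vapply(fit$outcomes, `[[`, 0, "r_squared"))
  names(r2) <- c("mediator", outcomes)
  b_paths <- data.frame(
    outcome = outcomes,
    estimate = vapply(fit$outcomes, `[[`, 0, "b"),
    se = vapply(fit$outcomes, `[[`, 0, "se_b"),
    std_estimate = if (is.null(zfit)) NA_real_
                   else vapply(zfit$outcomes, `[[`, 0, "b"),
    stringsAsFactors = FALSE)
  rownames(b_paths) <- NULL
  structure(
    list(paths = paths, r_squared = r2,
         a_paths = data.frame(predictor = predictors,
                              estimate = unname(fit$a),
                              se = unname(fit$se_a),
                              std_estimate = if (is.null(zfit)) NA_real_
                                             else unname(zfit$a),
                              stringsAsFactors = FALSE),
         b_paths = b_paths,
         n = n, n_outcome = vapply(fit$outcomes, `[[`, 0L, "n"),
         n_boot = n_boot, n_boot_achieved = achieved, conf = conf,
         predictors = predictors, mediator = mediator, outcomes = outcomes),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf(
    "Bootstrap mediation through %s (n = %d; CI based on %d of %d resamples)\n",
    x$mediator, x$n, x$n_boot_achieved, x$n_boot))
  df <- x$paths
  df$estimate <- signif(df$estimate, 3)
  df$ci <- sprintf("[%.3g, %.3g]", df$ci_lower, df$ci_upper)
  print(df[, c("predictor", "outcome", "effect", "estimate", "ci")],
        row.names = FALSE)
  cat("R-squared:", paste(sprintf("%s = %.2f", names(x$r_squared),
                                  x$r_squared), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) {
  cat(sprintf("Mediator equation %s ~ %s (R^2 = %.3f)\n", object$mediator,
              paste(object$predictors, collapse = " + "),
              object$r_squared["mediator"]))
  print(object$a_paths, row.names = FALSE)
  cat("\nMediator-to-outcome (b) paths:\n")
  print(object$b_paths, row.names = FALSE)
  cat("\nPath decomposition (total = direct + indirect):\n")
  print(object$paths, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.mediation_fit <- function(object, ...) {
  stats::setNames(object$paths$estimate,
                  paste(object$paths$effect, object$paths$predictor,
                        object$paths$outcome, sep = "."))
}
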