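# Statistical analysis of the mixed-phase Navon switching task and its
# relation to movement counts and stress: shift/nonshift tagging, condition
# summaries, Greenhouse-Geisser corrected repeated-measures ANOVA,
# pooled-error pairwise comparisons, pairwise-deletion correlations, and a
# bias-corrected percentile bootstrap mediation model.

#' Tag mixed-phase trials as shift or nonshift
#'
#' A trial is a *shift* trial when its target level (global/local) differs
#' from the preceding trial's, *nonshift* when it matches. The first trial
#' has no predecessor and is tagged `undefined`, excluded from both sets.
#'
#' @param kinds Character/factor vector of trial kinds, each `"global"` or
#'   `"local"`, in presentation order.
#' @return Factor with levels `shift`, `nonshift`, `undefined`, same length
#'   as `kinds`.
#' @examples
#' tag_shift_trials(c("global", "local", "local", "global"))
#' @export
tag_shift_trials <- function(kinds) {
  kinds <- as.character(kinds)
  if (length(kinds) == 0L) stop("empty trial sequence", call. = FALSE)
  bad <- setdiff(unique(kinds), c("global", "local"))
  if (length(bad) > 0L) {
    stop("trial kinds must be 'global' or 'local'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tags <- c("undefined",
            ifelse(kinds[-1] != kinds[-length(kinds)], "shift", "nonshift"))
  factor(tags, levels = c("shift", "nonshift", "undefined"))
}

#' Per-subject condition summaries of Navon trials
#'
#' Computes, for each participant, mean reaction times on *accurate* trials
#' in the four conditions (global phase, local phase, mixed nonshift, mixed
#' shift) plus the shift-trial accuracy rate. The first mixed trial is
#' `undefined` and excluded. Subjects without a single accurate trial in
#' some condition get `NA` there (no imputation), with a message.
#'
#' @param trials Data.frame with columns `participant`, `phase` (one of
#'   `global`, `local`, `mixed`), `trial_kind` (`global`/`local`; the target
#'   level, used in the mixed phase), `rt` (ms, > 0), `correct` (logical),
#'   and `trial` (presentation index within phase).
#' @return Data.frame, one row per participant: `participant`, `rt_global`,
#'   `rt_local`, `rt_nonshift`, `rt_shift`, `accuracy` (correct shift
#'   trials / shift trials), `n_shift`.
#' @export
condition_summaries <- function(trials) {
  needed <- c("participant", "phase", "trial_kind", "rt", "correct", "trial")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trials is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(trials$rt <= 0, na.rm = TRUE)) {
    stop("reaction times must be positive", call. = FALSE)
  }
  acc_mean <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  out <- lapply(split(trials, trials$participant), function(d) {
    g <- d[d$phase == "global", ]
    l <- d[d$phase == "local", ]
    m <- d[d$phase == "mixed", ]
    m <- m[order(m$trial), ]
    tags <- if (nrow(m) > 0L) tag_shift_trials(m$trial_kind) else factor()
    shift <- m[tags == "shift", ]
    nonshift <- m[tags == "nonshift", ]
    data.frame(
      participant = d$participant[1],
      rt_global = acc_mean(g$rt[g$correct]),
      rt_local = acc_mean(l$rt[l$correct]),
      rt_nonshift = acc_mean(nonshift$rt[nonshift$correct]),
      rt_shift = acc_mean(shift$rt[shift$correct]),
      accuracy = if (nrow(shift) == 0L) NA_real_
                 else mean(shift$correct),
      n_shift = nrow(shift),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  incomplete <- out$participant[!stats::complete.cases(
    out[, c("rt_global", "rt_local", "rt_nonshift", "rt_shift")])]
  if (length(incomplete) > 0L) {
    message("participants with missing condition means (no accurate trial): ",
            paste(incomplete, collapse = ", "))
  }
  out
}

#' Extract the subject x condition RT matrix
#'
#' @param summaries Output of [condition_summaries()].
#' @return Numeric matrix (subjects x 4) with columns `global`, `local`,
#'   `nonshift`, `shift`; rows with any missing condition are dropped.
#' @export
condition_matrix <- function(summaries) {
  m <- as.matrix(summaries[, c("rt_global", "rt_local", "rt_nonshift",
                               "rt_shift")])
  colnames(m) <- c("global", "local", "nonshift", "shift")
  rownames(m) <- summaries$participant
  m[stats::complete.cases(m), , drop = FALSE]
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject decomposition of an `n x k` complete matrix
#' (subjects x conditions). The Greenhouse-Geisser epsilon is computed from
#' the double-centred condition covariance matrix,
#' `eps = tr(S)^2 / ((k-1) * tr(S^2))`, and applied multiplicatively to both
#' degrees of freedom; the p value comes from the F distribution at the
#' corrected (fractional) dfs. Effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param mat Complete numeric matrix, `n >= 2` subjects by `k >= 2`
#'   conditions. Missing cells are an error (no imputation).
#' @return An `rm_anova_gg` object: `F`, `df1`, `df2` (GG-corrected,
#'   fractional), `epsilon`, `p`, `eta_sq`, `ms_error`, `n`, `k`,
#'   `means` and the uncorrected dfs.
#' @export
rm_anova_gg <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix contains missing cells", call. = FALSE)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions",
                             call. = FALSE)
  grand <- mean(mat)
  cond_means <- colMeans(mat)
  subj_means <- rowMeans(mat)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1_raw <- k - 1
  df2_raw <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1_raw
  ms_err <- ss_err / df2_raw
  Fval <- ms_cond / ms_err
  # GG epsilon from the double-centred covariance of conditions
  S <- stats::cov(mat)
  C <- diag(k) - matrix(1 / k, k, k)
  Sc <- C %*% S %*% C
  eps <- sum(diag(Sc))^2 / (df1_raw * sum(Sc * Sc))
  eps <- min(1, max(1 / df1_raw, eps))
  df1 <- eps * df1_raw
  df2 <- eps * df2_raw
  structure(
    list(F = Fval, df1 = df1, df2 = df2, epsilon = eps,
         p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
         eta_sq = ss_cond / (ss_cond + ss_err),
         ss_cond = ss_cond, ss_error = ss_err, ms_error = ms_err,
         df1_uncorrected = df1_raw, df2_uncorrected = df2_raw,
         n = n, k = k, means = cond_means),
    class = "rm_anova_gg"
  )
}

#' @export
print.rm_anova_gg <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA (Greenhouse-Geisser corrected, eps = %.3f)\n",
    x$epsilon))
  cat(sprintf("  F(%.2f, %.2f) = %.2f, p = %s, partial eta^2 = %.2f\n",
              x$df1, x$df2, x$F, format.pval(x$p, digits = 3), x$eta_sq))
  invisible(x)
}

#' Pairwise comparisons of within-subject condition means
#'
#' All `k(k-1)/2` pairs, using the common pooled standard error from the
#' repeated-measures ANOVA error term, `SE = sqrt(2 * MS_error / n)`, with
#' `t = difference / SE` on `(n-1)(k-1)` degrees of freedom. Both
#' Bonferroni (multiplied by the number of pairs, capped at 1) and Holm
#' step-down adjusted p values are reported.
#'
#' @param mat Complete subjects x conditions matrix, as in [rm_anova_gg()].
#' @return Data.frame with one row per pair: `cond1`, `cond2`,
#'   `mean_difference` (cond1 - cond2), `se`, `t`, `df`, `p`, `p_bonf`,
#'   `p_holm`.
#' @export
pairwise_comparisons <- function(mat) {
  mat <- as.matrix(mat)
  aov_res <- rm_anova_gg(mat)
  n <- aov_res$n; k <- aov_res$k
  se <- sqrt(2 * aov_res$ms_error / n)
  df <- aov_res$df2_uncorrected
  conds <- colnames(mat)
  if (is.null(conds)) conds <- paste0("C", seq_len(k))
  pairs <- utils::combn(k, 2)
  means <- colMeans(mat)
  out <- data.frame(
    cond1 = conds[pairs[1, ]], cond2 = conds[pairs[2, ]],
    mean_difference = means[pairs[1, ]] - means[pairs[2, ]],
    se = se, stringsAsFactors = FALSE)
  out$t <- out$mean_difference / se
  out$df <- df
  out$p <- 2 * stats::pt(abs(out$t), df, lower.tail = FALSE)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Pairwise-deletion Pearson correlation matrix
#'
#' Pearson r for every variable pair over the pairwise-complete
#' observations, with two-sided p values from
#' `t = r * sqrt((n-2) / (1-r^2))`. Pairs with fewer than 3 complete
#' observations or a zero-variance column are reported as `NA`.
#'
#' @param data Data.frame or matrix of numeric variables (missing values
#'   allowed; deleted pairwise).
#' @return A `cor_matrix` object: list of symmetric matrices `r`, `p`, `n`.
#' @export
correlation_matrix <- function(data) {
  data <- as.data.frame(data)
  data <- data[vapply(data, is.numeric, TRUE)]
  v <- names(data)
  k <- length(v)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(v, v))
  diag(r) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      ok <- stats::complete.cases(data[[i]], data[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L || stats::sd(data[[i]][ok]) == 0 ||
          stats::sd(data[[j]][ok]) == 0) next
      ct <- stats::cor.test(data[[i]][ok], data[[j]][ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(nmat) <- colSums(!is.na(data))
  structure(list(r = r, p = p, n = nmat), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Pearson correlations (r):\n")
  print(round(x$r, digits))
  invisible(x)
}
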