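# Shift/nonshift tagging, condition summaries, GG-corrected RM-ANOVA,
# pairwise comparisons and correlations.

test_that("shift tagging follows the switch definition", {
  tags <- tag_shift_trials(c("global", "local", "local", "global"))
  expect_equal(as.character(tags),
               c("undefined", "shift", "nonshift", "shift"))
  same <- tag_shift_trials(rep("global", 40))
  expect_equal(sum(same == "nonshift"), 39L)
  expect_equal(sum(same == "shift"), 0L)
  alt <- tag_shift_trials(rep(c("global", "local"), 20))
  expect_equal(sum(alt == "shift"), 39L)
  expect_error(tag_shift_trials(character(0)), "empty")
  expect_error(tag_shift_trials(c("global", "mixed")), "global")
})

test_that("tagging partitions every sequence with one undefined trial", {
  set.seed(5)
  for (i in 1:20) {
    kinds <- sample(c("global", "local"), sample(2:60, 1), replace = TRUE)
    tags <- tag_shift_trials(kinds)
    expect_equal(length(tags), length(kinds))
    expect_equal(sum(tags == "undefined"), 1L)
    expect_equal(sum(tags == "shift") + sum(tags == "nonshift") + 1L,
                 length(kinds))
  }
})

test_that("condition summaries average accurate trials only", {
  trials <- data.frame(
    participant = "P1",
    phase = c("global", "global", "mixed", "mixed", "mixed", "mixed"),
    trial_kind = c("global", "global", "global", "local", "global", "local"),
    rt = c(500, 700, 800, 1000, 2000, 9000),
    correct = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    trial = c(1, 2, 1, 2, 3, 4))
  s <- suppressMessages(condition_summaries(trials))
  # mixed kinds G,L,G,L -> tags undefined, shift, shift, shift
  expect_equal(s$rt_shift, mean(c(1000, 2000)))  # 9000 is inaccurate
  expect_equal(s$accuracy, 2 / 3)
  expect_equal(s$n_shift, 3L)
  expect_equal(s$rt_global, 600)
  expect_true(is.na(s$rt_nonshift))
})

test_that("all-correct trials give accuracy 1", {
  tr <- generate_trials(navon_trial_config(n_subjects = 3, p_correct = 1),
                        seed = 2)
  s <- condition_summaries(tr)
  expect_true(all(s$accuracy == 1))
  expect_true(all(stats::complete.cases(s)))
})

test_that("simulated condition means recover requested values within 3 SEM", {
  cfg <- navon_trial_config(n_subjects = 120)
  s <- condition_summaries(generate_trials(cfg, seed = 31))
  m <- condition_matrix(s)
  for (cond in colnames(m)) {
    sem <- stats::sd(m[, cond]) / sqrt(nrow(m))
    expect_lt(abs(mean(m[, cond]) - cfg$condition_means[cond]), 3 * sem +
                0.05 * cfg$condition_means[cond])
  }
})

test_that("two-condition RM-ANOVA reduces to the squared paired t", {
  set.seed(9)
  m <- cbind(a = rnorm(15, 10), b = rnorm(15, 11))
  res <- rm_anova_gg(m)
  tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(res$epsilon, 1)
  expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("GG epsilon and F agree with car's multivariate machinery", {
  skip_if_not_installed("car")
  set.seed(17)
  n <- 20; k <- 4
  base <- matrix(rnorm(n * k), n, k)
  m <- base + rnorm(n) + matrix(rnorm(n * k, sd = c(0.5, 1, 2, 3)), n, k,
                                byrow = TRUE)
  colnames(m) <- paste0("c", 1:k)
  res <- rm_anova_gg(m)
  fit <- stats::lm(m ~ 1)
  idata <- data.frame(cond = factor(paste0("c", 1:k)))
  av <- car::Anova(fit, idata = idata, idesign = ~cond, type = 3)
  sm <- summary(av)
  expect_equal(res$epsilon, unname(sm$pval.adjustments[1, "GG eps"]),
               tolerance = 1e-8)
  expect_equal(res$F, unname(sm$univariate.tests["cond", "F value"]),
               tolerance = 1e-8)
})

test_that("null data produce uniform p values (KS at alpha = 0.01)", {
  set.seed(23)
  ps <- replicate(500, rm_anova_gg(matrix(rnorm(10 * 3), 10, 3))$p)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("spherical iid data keep epsilon near 1", {
  set.seed(29)
  eps <- replicate(2000, rm_anova_gg(matrix(rnorm(28 * 4), 28, 4))$epsilon)
  expect_gte(stats::median(eps), 0.9)
})

test_that("epsilon respects its analytic bounds and the df identities", {
  set.seed(37)
  for (i in 1:10) {
    k <- sample(3:5, 1); n <- sample(8:30, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n)
    res <- rm_anova_gg(m)
    expect_gte(res$epsilon, 1 / (k - 1) - 1e-12)
    expect_lte(res$epsilon, 1)
    expect_equal(res$df1, res$epsilon * (k - 1))
    expect_equal(res$df2, res$epsilon * (k - 1) * (n - 1))
  }
  expect_error(rm_anova_gg(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("pairwise comparisons use the pooled error and both corrections", {
  set.seed(41)
  m <- matrix(rnorm(28 * 4, mean = c(930, 1100, 1345, 1470)), 28, 4,
              byrow = TRUE)
  colnames(m) <- c("global", "local", "nonshift", "shift")
  res <- pairwise_comparisons(m)
  expect_equal(nrow(res), 6L)
  aovr <- rm_anova_gg(m)
  expect_equal(unique(res$se), sqrt(2 * aovr$ms_error / 28))
  expect_equal(res$t, res$mean_difference / res$se)
  expect_equal(res$df, rep(27 * 3, 6))
  expect_equal(res$p_bonf, pmin(1, res$p * 6))
  expect_equal(res$p_holm, stats::p.adjust(res$p, "holm"))
  # identical columns give zero difference, t = 0, p_bonf = 1
  m2 <- cbind(m[, 1], m[, 1], m[, 3], m[, 4])
  r2 <- pairwise_comparisons(m2)
  expect_equal(r2$mean_difference[1], 0)
  expect_equal(r2$t[1], 0)
  expect_equal(r2$p_bonf[1], 1)
})

test_that("correlation matrix handles exact and degenerate cases", {
  x <- rnorm(20)
  df <- data.frame(x = x, negx = -x, z = rnorm(20))
  res <- correlation_matrix(df)
  expect_equal(diag(res$r), c(x = 1, negx = 1, z = 1))
  expect_equal(res$r["x", "negx"], -1)
  expect_lt(res$p["x", "negx"], 1e-12)
  expect_equal(res$r, t(res$r))
  # zero-variance column reported missing
  df$const <- 1
  res2 <- correlation_matrix(df)
  expect_true(all(is.na(res2$r["const", c("x", "z")])))
})

test_that("pairwise deletion uses the available pairs", {
  set.seed(43)
  df <- data.frame(a = rnorm(30), b = rnorm(30), s = rnorm(30))
  df$s[1:4] <- NA
  res <- correlation_matrix(df)
  expect_equal(res$n["a", "s"], 26)
  expect_equal(res$n["a", "b"], 30)
  ct <- stats::cor.test(df$a[-(1:4)], df$s[-(1:4)])
  expect_equal(res$r["a", "s"], unname(ct$estimate))
})

test_that("correlation estimates are unbiased at rho = 0.5", {
  set.seed(47)
  rho <- 0.5
  rs <- replicate(1000, {
    x <- rnorm(28)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(28)
    correlation_matrix(data.frame(x = x, y = y))$r["x", "y"]
  })
  expect_lt(abs(mean(rs) - rho), 0.03)
})
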