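# Bootstrap mediation: path algebra, delta/bootstrap inference, missing
# stress handling and cross-checks against lm().

planted_config <- function(a_swing = -5, b_acc = -0.0005,
                           rt_sd = 30, acc_sd = 0.01) {
  exp2_config(n_subjects = 200,
              a = c(swinging = a_swing, rotating = 0, sitting = 0),
              b_accuracy = b_acc, rt_sd = rt_sd, accuracy_sd = acc_sd,
              stress_sd = 2, missing_stress_prob = 0)
}

test_that("total equals direct plus indirect exactly on every fit", {
  for (seed in 1:5) {
    dat <- generate_exp2_dataset(exp2_config(n_subjects = 40), seed = seed)
    fit <- mediate_boot(dat, n_boot = 50, seed = seed)
    p <- fit$paths
    for (xv in fit$predictors) {
      for (yv in fit$outcomes) {
        rows <- p[p$predictor == xv & p$outcome == yv, ]
        expect_equal(rows$estimate[rows$effect == "total"],
                     rows$estimate[rows$effect == "direct"] +
                       rows$estimate[rows$effect == "indirect"],
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("path coefficients match lm() on the same equations", {
  dat <- generate_exp2_dataset(exp2_config(n_subjects = 60), seed = 12)
  fit <- mediate_boot(dat, n_boot = 30, seed = 1)
  med_lm <- stats::lm(reaction_time ~ swinging + rotating + sitting,
                      data = dat)
  expect_equal(fit$a_paths$estimate,
               unname(stats::coef(med_lm)[c("swinging", "rotating",
                                            "sitting")]),
               tolerance = 1e-10)
  expect_equal(fit$a_paths$se,
               unname(summary(med_lm)$coefficients[c("swinging", "rotating",
                                                     "sitting"), 2]),
               tolerance = 1e-8)
  expect_equal(unname(fit$r_squared["mediator"]),
               summary(med_lm)$r.squared, tolerance = 1e-10)
  out_lm <- stats::lm(accuracy ~ reaction_time + swinging + rotating +
                        sitting, data = dat)
  direct <- fit$paths[fit$paths$outcome == "accuracy" &
                        fit$paths$effect == "direct", ]
  expect_equal(direct$estimate,
               unname(stats::coef(out_lm)[c("swinging", "rotating",
                                            "sitting")]),
               tolerance = 1e-10)
})

test_that("planted effects are recovered with correct signs and coverage", {
  dat <- generate_exp2_dataset(planted_config(), seed = 7)
  fit <- mediate_boot(dat, n_boot = 400, seed = 99)
  ind <- fit$paths[fit$paths$predictor == "swinging" &
                     fit$paths$outcome == "accuracy" &
                     fit$paths$effect == "indirect", ]
  expect_equal(ind$estimate, (-5) * (-0.0005), tolerance = 0.3)
  expect_gt(ind$estimate, 0)
  expect_true(ind$ci_lower <= ind$estimate && ind$estimate <= ind$ci_upper)
  dir <- fit$paths[fit$paths$predictor == "swinging" &
                     fit$paths$outcome == "accuracy" &
                     fit$paths$effect == "direct", ]
  expect_true(dir$ci_lower <= 0 && 0 <= dir$ci_upper)
})

test_that("bootstrap CIs are reproducible under the seed", {
  dat <- generate_exp2_dataset(exp2_config(n_subjects = 30), seed = 3)
  f1 <- mediate_boot(dat, n_boot = 100, seed = 42)
  f2 <- mediate_boot(dat, n_boot = 100, seed = 42)
  expect_identical(f1$paths, f2$paths)
  f3 <- mediate_boot(dat, n_boot = 100, seed = 43)
  expect_false(identical(f1$paths$ci_lower, f3$paths$ci_lower))
})

test_that("rows missing stress are excluded from stress equations only", {
  dat <- generate_exp2_dataset(exp2_config(n_subjects = 40,
                                           missing_stress_prob = 0),
                               seed = 5)
  dat$stress[1:6] <- NA
  fit <- mediate_boot(dat, n_boot = 30, seed = 1)
  expect_equal(unname(fit$n_outcome["accuracy"]), 40L)
  expect_equal(unname(fit$n_outcome["stress"]), 34L)
  expect_equal(fit$n, 40L)
  # stress b-path must equal lm on the complete-stress subset
  sub <- dat[!is.na(dat$stress), ]
  lm_s <- stats::lm(stress ~ reaction_time + swinging + rotating + sitting,
                    data = sub)
  b <- fit$b_paths$estimate[fit$b_paths$outcome == "stress"]
  expect_equal(b, unname(stats::coef(lm_s)["reaction_time"]),
               tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  dat <- generate_exp2_dataset(exp2_config(n_subjects = 20), seed = 2)
  expect_error(mediate_boot(dat[1:5, ]), "at least 10")
  bad <- dat
  bad$rotating <- bad$swinging  # collinear predictors
  expect_error(mediate_boot(bad, n_boot = 10), "singular")
  expect_error(mediate_boot(dat[setdiff(names(dat), "swinging")],
                            n_boot = 10), "missing column")
})

test_that("standardised estimates equal the raw estimates rescaled", {
  dat <- generate_exp2_dataset(planted_config(), seed = 9)
  fit <- mediate_boot(dat, n_boot = 30, seed = 1)
  ind <- fit$paths[fit$paths$predictor == "swinging" &
                     fit$paths$outcome == "accuracy" &
                     fit$paths$effect == "indirect", ]
  manual <- ind$estimate * stats::sd(dat$swinging) / stats::sd(dat$accuracy)
  expect_equal(ind$std_estimate, manual, tolerance = 1e-8)
})
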