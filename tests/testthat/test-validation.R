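test_that("observations match the nearest grid point and skip aberrant ones", {
  p <- default_pk_params()
  prof <- predict_profile(zuspan_schedule(treatment_end = 24), p, horizon = 24)
  obs <- data.frame(time = c(1.02, 4.0, 8.01), conc = c(1.5, 1.7, 7.28),
                    aberrant = c(FALSE, FALSE, TRUE))
  pairs <- match_predictions(prof, obs)
  expect_equal(nrow(pairs), 2)                       # aberrant excluded
  expect_equal(pairs$pred_time[1], 1.0, tolerance = 1e-9)  # nearest 5-min point
  expect_true(all(abs(pairs$time - pairs$pred_time) <= 1 / 24 + 1e-12))
  expect_equal(pairs$error, pairs$measured - pairs$predicted)

  expect_equal(nrow(match_predictions(prof, obs[0, ])), 0)
  expect_warning(match_predictions(prof, data.frame(time = 30, conc = 2)),
                 "beyond the profile horizon")
})

test_that("every non-aberrant observation yields exactly one matched pair", {
  coh <- simulate_cohort(12, seed = 3,
                         error = error_model(outlier_prob = 0))
  pairs <- validate_predictions(coh)
  n_obs <- sum(vapply(coh$cases, function(cs) nrow(cs$observations), integer(1)))
  expect_equal(nrow(pairs), n_obs)
  expect_equal(anyDuplicated(pairs[c("case_id", "time")]), 0)
})

test_that("mean prediction error and its t interval are correct", {
  mk <- function(e) data.frame(case_id = paste0("C", seq_along(e)),
                               measured = 2 + e, predicted = 2, error = e)
  # measured == predicted everywhere: zero mean, zero-width interval
  r0 <- mean_prediction_error(mk(c(0, 0, 0)))
  expect_equal(r0$mean, 0)
  expect_equal(r0$ci, c(0, 0))

  # hand-checked t interval: errors {-0.2, 0, 0.2}, df = 2
  r <- mean_prediction_error(mk(c(-0.2, 0, 0.2)))
  expect_equal(r$mean, 0)
  half <- qt(0.975, 2) * sd(c(-0.2, 0, 0.2)) / sqrt(3)
  expect_equal(r$ci, c(-half, half))
  expect_equal(half, 0.4968, tolerance = 1e-3)

  expect_error(mean_prediction_error(mk(0.1)), "at least 2")

  # clustered variant averages within case first
  pr <- data.frame(case_id = c("A", "A", "A", "B"),
                   error = c(0.1, 0.1, 0.1, -0.1))
  rc <- mean_prediction_error(pr, cluster = TRUE)
  expect_equal(rc$mean, 0)
  expect_equal(rc$n, 2)
})

test_that("an injected constant bias is recovered exactly under zero noise", {
  em <- error_model(prop_cv = 0, add_sd = 0, outlier_prob = 0, bias = -0.10)
  coh <- simulate_cohort(15, seed = 8, error = em)
  pairs <- validate_predictions(coh)
  r <- mean_prediction_error(pairs)
  expect_equal(r$mean, -0.10, tolerance = 1e-9)
})

test_that("bias regression matches the normal-equations oracle", {
  pairs <- data.frame(error = c(0.05, 0.05, 0.05, 0.05),
                      weight = c(60, 75, 90, 110))
  expect_equal(suppressWarnings(bias_regression(pairs, "weight"))$slope, 0,
               tolerance = 1e-12)

  pairs2 <- data.frame(error = 2 * c(60, 75, 90, 110),
                       weight = c(60, 75, 90, 110))
  r2 <- suppressWarnings(bias_regression(pairs2, "weight"))  # exact fit
  expect_equal(r2$slope, 2, tolerance = 1e-10)
  expect_lt(r2$p, 1e-10)

  set.seed(14)
  x <- runif(20, 50, 110)
  y <- 0.01 * x + rnorm(20, 0, 0.1)
  r3 <- bias_regression(data.frame(error = y, weight = x), "weight")
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (20 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(r3$slope, unname(beta[2, 1]), tolerance = 1e-10)
  expect_equal(r3$se, se, tolerance = 1e-10)
})

test_that("calibration table bins predictions and exposes miscalibration", {
  set.seed(2)
  pred <- runif(400, 1, 3)
  pairs <- data.frame(predicted = pred, measured = pred)
  tab <- calibration_table(pairs, n_bins = 8)
  expect_true(all(abs(tab$mean_measured - tab$midpoint) < 0.15))
  expect_equal(sum(tab$n), 400)

  one <- calibration_table(data.frame(predicted = 2, measured = 1.9))
  expect_equal(nrow(one), 1)
  expect_equal(one$n, 1)

  mis <- data.frame(predicted = pred, measured = 0.9 * pred)
  tabm <- calibration_table(mis, n_bins = 8)
  slope <- coef(lm(mean_measured ~ midpoint, data = tabm, weights = tabm$n))[2]
  expect_equal(unname(slope), 0.9, tolerance = 0.02)
})

test_that("treatment-period bins partition the first 60 hours", {
  expect_equal(as.character(period_bin(c(0, 3.9))), c("early", "early"))
  expect_equal(as.character(period_bin(c(4, 16.5))),
               c("intermediate", "intermediate"))
  expect_equal(as.character(period_bin(c(17, 24.9))), c("late", "late"))
  expect_equal(as.character(period_bin(c(25, 60))), c("extended", "extended"))
  expect_true(is.na(period_bin(61)))
  # no gaps, no overlaps
  grid <- seq(0, 60, by = 0.01)
  expect_false(anyNA(period_bin(grid)))
})

test_that("period summary recovers constructed rate and concentration shifts", {
  set.seed(6)
  cases <- lapply(1:10, function(i) {
    r_early <- 1.0 + rnorm(1, 0, 0.03)
    r_mid <- 1.5 + rnorm(1, 0, 0.03)
    sched <- zuspan_schedule(initial_rate = r_early,
                             rate_changes = data.frame(time = 4, rate = r_mid),
                             treatment_end = 16)
    obs <- data.frame(time = c(1, 2, 3, 5, 8, 12),
                      conc = c(1.5, 1.5, 1.5, 1.74, 1.74, 1.74) +
                        rnorm(6, 0, 0.05))
    case_record(paste0("P", i), 84, 57, sched, obs)
  })
  coh <- mg_cohort(cases)
  pairs <- validate_predictions(coh, flag = FALSE)
  ps <- period_summary(coh, pairs)
  s <- ps$summary
  expect_equal(s$n[s$period == "early"], 30)
  expect_equal(s$n[s$period == "intermediate"], 30)
  expect_equal(s$mean_rate[s$period == "early"], 1.0, tolerance = 0.05)
  expect_equal(s$mean_rate[s$period == "intermediate"], 1.5, tolerance = 0.05)
  expect_equal(s$n[s$period == "late"], 0)
  cmp <- ps$comparisons
  expect_equal(nrow(cmp), 1)   # only adjacent non-empty bins compared
  expect_lt(cmp$rate_p, 1e-6)
  expect_lt(cmp$conc_p, 1e-6)
  expect_gt(cmp$conc_diff, 0.1)
})

test_that("aberrant spikes are flagged only with a confirming rebound", {
  # spike followed by return to previous level: flagged
  f1 <- flag_aberrant(data.frame(time = 1:3, conc = c(1.8, 7.28, 1.9)))
  expect_equal(f1$aberrant, c(FALSE, TRUE, FALSE))

  # monotone plausible series: nothing flagged
  f2 <- flag_aberrant(data.frame(time = 1:3, conc = c(1.5, 1.8, 2.1)))
  expect_false(any(f2$aberrant))

  # exceedance on the last sample: manual review, never auto-flagged
  f3 <- flag_aberrant(data.frame(time = 1:3, conc = c(1.8, 1.9, 4.0)))
  expect_false(any(f3$aberrant))
  expect_equal(attr(f3, "manual_review"), 3L)

  # rebound outside the lookahead window does not confirm the spike
  f4 <- flag_aberrant(data.frame(time = c(1, 2, 10), conc = c(1.8, 7.28, 1.9)))
  expect_false(any(f4$aberrant))
  expect_equal(attr(f4, "manual_review"), 2L)

  # a sustained plateau just above the threshold is not a spike
  f5 <- flag_aberrant(data.frame(time = 1:4, conc = c(3.3, 3.6, 3.65, 3.6)))
  expect_false(any(f5$aberrant))
})

test_that("toxicity screening lists exceedances with resolution status", {
  clean <- simulate_cohort(20, seed = 12,
                           protocol = protocol_config(titration_threshold = 0),
                           error = error_model(outlier_prob = 0))
  expect_equal(nrow(screen_toxicity(clean)), 0)

  spike_case <- case_record("T1", 84, 57,
                            zuspan_schedule(treatment_end = 24),
                            data.frame(time = c(1, 2, 3),
                                       conc = c(1.8, 7.28, 1.9)))
  final_case <- case_record("T2", 84, 57,
                            zuspan_schedule(treatment_end = 24),
                            data.frame(time = c(1, 2), conc = c(1.8, 4.0)))
  tox <- screen_toxicity(mg_cohort(list(spike_case, final_case)))
  expect_equal(nrow(tox), 2)
  expect_true(tox$resolved_by_resample[tox$case_id == "T1"])
  expect_false(tox$resolved_by_resample[tox$case_id == "T2"])
})

test_that("zero-noise closure: validating against the generating model", {
  coh <- simulate_cohort(10, seed = 5, error = zero_error_model())
  pairs <- validate_predictions(coh)
  expect_lt(abs(mean_prediction_error(pairs)$mean), 1e-9)
  for (cv in c("weight", "creatinine", "duration")) {
    expect_lt(abs(bias_regression(pairs, cv)$slope), 1e-9)
  }
})
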