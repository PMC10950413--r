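test_that("hybrid constants are the roots of the disposition quadratic", {
  # symmetric toy model: k10 = k12 = k21 = 1, roots (3 +/- sqrt(5)) / 2
  hc <- hybrid_constants(pk_params(CL = 1, V1 = 1, Q = 1, V2 = 1))
  expect_equal(unname(hc[["alpha"]]), (3 + sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(unname(hc[["beta"]]), (3 - sqrt(5)) / 2, tolerance = 1e-12)

  # independent polynomial-root oracle
  p <- pk_params(CL = 4, V1 = 20, Q = 2, V2 = 30)
  hc <- hybrid_constants(p)
  roots <- sort(Re(polyroot(c(p$k10 * p$k21, p$k10 + p$k12 + p$k21, 1))))
  expect_equal(unname(hc[["beta"]]), -roots[2], tolerance = 1e-10)
  expect_equal(unname(hc[["alpha"]]), -roots[1], tolerance = 1e-10)

  # Vieta identities on random parameter sets
  set.seed(11)
  for (i in 1:20) {
    p <- rand_params()
    hc <- hybrid_constants(p)
    expect_equal(hc[["alpha"]] * hc[["beta"]], (p$CL / p$V1) * (p$Q / p$V2),
                 tolerance = 1e-12)
    expect_equal(hc[["alpha"]] + hc[["beta"]], p$k10 + p$k12 + p$k21,
                 tolerance = 1e-12)
    expect_true(hc[["alpha"]] > hc[["beta"]] && hc[["beta"]] > 0)
  }

  expect_error(hybrid_constants(pk_params(CL = 4, V1 = 20, Q = 0, V2 = 30)),
               "degenerate")
})

test_that("infusion response: zero input, steady-state limit, ODE agreement", {
  p <- default_pk_params()
  expect_equal(infusion_response(0, c(0, 1, 50), p), c(0, 0, 0))
  expect_error(infusion_response(1, -1, p), ">= 0")

  # monotone nondecreasing and bounded by rate/CL
  tt <- seq(0, 400, by = 0.5)
  resp <- infusion_response(4.06, tt, p)
  expect_true(all(diff(resp) >= -1e-12))
  beta <- hybrid_constants(p)[["beta"]]
  expect_equal(infusion_response(4.06, 200 / beta, p), 4.06 / p$CL,
               tolerance = 1e-9)

  # ODE-integrator oracle at several times, random params and rates
  set.seed(21)
  for (i in 1:5) {
    pr <- rand_params()
    rate_g <- runif(1, 0.5, 2)
    sched <- zuspan_schedule(bolus_dose = 1e-9, initial_rate = rate_g,
                             treatment_end = 24, bolus_duration = 1 / 3)
    for (t in c(0.5, 2, 10)) {
      closed <- infusion_response(rate_g * pr$dose_to_amount, t, pr)
      numeric_c <- ode_profile_oracle(sched, pr, t) - pr$baseline
      expect_equal(closed, numeric_c, tolerance = 1e-6)
    }
  }
})

test_that("predict_profile superposes boluses and rate changes correctly", {
  p <- default_pk_params()

  # degenerate schedule: negligible dose, no maintenance -> flat baseline
  sched0 <- dosing_schedule(
    data.frame(time = 0, kind = "bolus", dose = 1e-300, rate = NA),
    treatment_end = 10)
  prof0 <- predict_profile(sched0, p, horizon = 10)
  expect_equal(prof0$conc, rep(0.74, nrow(prof0)), tolerance = 1e-12)

  # guideline schedule with a titration step vs the ODE oracle
  sched <- zuspan_schedule(bolus_dose = 4, initial_rate = 1,
                           rate_changes = data.frame(time = 5, rate = 1.25),
                           treatment_end = 24)
  prof <- predict_profile(sched, p, resolution = 0.25, horizon = 30)
  oracle <- ode_profile_oracle(sched, p, prof$time)
  expect_lt(max(abs(prof$conc - oracle)), 1e-6)

  # grid is uniform, starts at 0, concentrations never below baseline
  expect_equal(prof$time[1], 0)
  expect_equal(diff(prof$time), rep(0.25, nrow(prof) - 1))
  expect_true(all(prof$conc >= p$baseline - 1e-12))
})

test_that("drug-attributable concentration is linear in the schedule", {
  p <- default_pk_params()
  a <- zuspan_schedule(bolus_dose = 4, initial_rate = 1, treatment_end = 24)
  b <- zuspan_schedule(bolus_dose = 2, initial_rate = 0.5,
                       rate_changes = data.frame(time = 6, rate = 1),
                       treatment_end = 24)
  tt <- seq(0, 30, by = 0.5)
  ca <- conc_at(a, p, tt) - p$baseline
  cb <- conc_at(b, p, tt) - p$baseline
  sum_sched <- zuspan_schedule(
    bolus_dose = 6, initial_rate = 1.5,
    rate_changes = data.frame(time = 6, rate = 2), treatment_end = 24)
  csum <- conc_at(sum_sched, p, tt) - p$baseline
  expect_equal(ca + cb, csum, tolerance = 1e-9)

  # doubling the bolus dose doubles the bolus-attributable concentration
  only_bolus <- function(d) {
    dosing_schedule(data.frame(time = 0, kind = "bolus", dose = d, rate = NA),
                    treatment_end = 10)
  }
  c1 <- conc_at(only_bolus(2), p, tt) - p$baseline
  c2 <- conc_at(only_bolus(4), p, tt) - p$baseline
  expect_equal(2 * c1, c2, tolerance = 1e-9)
})

test_that("short-bolus limit approaches the instantaneous peak dose/V1", {
  p <- default_pk_params()
  peak_inst <- p$baseline + 4 * p$dose_to_amount / p$V1
  for (dur in c(1 / 60, 1 / 600, 1 / 6000)) {
    sched <- dosing_schedule(
      data.frame(time = 0, kind = "bolus", dose = 4, rate = NA,
                 bolus_duration = dur), treatment_end = 1)
    peak <- conc_at(sched, p, dur)
    expect_lt(abs(peak - peak_inst), peak_inst * dur)  # converges linearly
  }
  # duration 0 evaluates the instantaneous closed form exactly
  sched0 <- dosing_schedule(
    data.frame(time = 0, kind = "bolus", dose = 4, rate = NA,
               bolus_duration = 0), treatment_end = 1)
  expect_equal(conc_at(sched0, p, 0), peak_inst, tolerance = 1e-12)
})

test_that("profiles are monotone in bolus dose and maintenance rates", {
  p <- default_pk_params()
  tt <- seq(0, 30, by = 0.5)
  base <- zuspan_schedule(bolus_dose = 4, initial_rate = 1,
                          rate_changes = data.frame(time = 5, rate = 1.25),
                          treatment_end = 24)
  up_bolus <- zuspan_schedule(bolus_dose = 5, initial_rate = 1,
                              rate_changes = data.frame(time = 5, rate = 1.25),
                              treatment_end = 24)
  up_rate <- zuspan_schedule(bolus_dose = 4, initial_rate = 1,
                             rate_changes = data.frame(time = 5, rate = 1.5),
                             treatment_end = 24)
  c0 <- conc_at(base, p, tt)
  expect_true(all(conc_at(up_bolus, p, tt) >= c0 - 1e-12))
  expect_true(all(conc_at(up_rate, p, tt) >= c0 - 1e-12))
})

test_that("steady_state formula and long-horizon convergence agree", {
  p <- pk_params(CL = 4, V1 = 20, Q = 2, V2 = 30)
  expect_equal(steady_state(0, p), p$baseline)
  expect_equal(steady_state(1, p), 0.74 + 4.06 / 4)  # 1.755

  sched <- zuspan_schedule(bolus_dose = 1e-300, initial_rate = 1,
                           treatment_end = 6000)
  beta <- hybrid_constants(p)[["beta"]]
  prof <- predict_profile(sched, p, resolution = 1, horizon = 210 / beta)
  expect_equal(prof$conc[nrow(prof)], steady_state(1, p), tolerance = 1e-6)
})

test_that("time_to_threshold is the first strict grid exceedance", {
  p <- default_pk_params()
  prof <- predict_profile(zuspan_schedule(treatment_end = 24), p, horizon = 24)
  expect_equal(time_to_threshold(prof, 0.5), 0)          # below baseline
  expect_true(is.na(time_to_threshold(prof, 100)))       # above global max

  # toy monotone profile crossing between grid points: coarse-grid answer is
  # the first grid point strictly above the dense-grid crossing
  sched <- zuspan_schedule(bolus_dose = 1e-300, initial_rate = 2,
                           treatment_end = 400)
  coarse <- predict_profile(sched, p, resolution = 1, horizon = 100)
  dense <- predict_profile(sched, p, resolution = 1 / 600, horizon = 100)
  thr <- 1.9
  t_coarse <- time_to_threshold(coarse, thr)
  t_dense <- time_to_threshold(dense, thr)
  expect_true(t_coarse >= t_dense)
  expect_equal(t_coarse, ceiling(t_dense))  # first integer grid point above
})

test_that("individualize applies covariate functions anchored at reference", {
  typ <- default_pk_params()
  cm <- default_covariate_model()
  # identity at the reference covariates
  at_ref <- individualize(typ, cm, cm$ref_weight, cm$ref_creatinine)
  expect_equal(at_ref$CL, typ$CL)
  expect_equal(at_ref$V1, typ$V1)
  expect_equal(at_ref$V2, typ$V2)

  # power form with exponent 1 on V1: doubling weight doubles V1
  dbl <- individualize(typ, cm, 2 * cm$ref_weight, cm$ref_creatinine)
  expect_equal(dbl$V1, 2 * typ$V1)

  # directionality: CL decreasing in creatinine, volumes increasing in weight
  lo_crea <- individualize(typ, cm, cm$ref_weight, 40)
  hi_crea <- individualize(typ, cm, cm$ref_weight, 90)
  expect_gt(lo_crea$CL, hi_crea$CL)
  heavy <- individualize(typ, cm, 110, cm$ref_creatinine)
  expect_gt(heavy$V1, typ$V1)
  expect_gt(heavy$CL, typ$CL)

  expect_error(individualize(typ, cm, -1, 60), "weight")
  expect_error(individualize(typ, cm, 70, 0), "creatinine")
})
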