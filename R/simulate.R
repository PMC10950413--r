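#' Treatment-protocol configuration (Zuspan regimen with titration)
#'
#' The guideline protocol the generator emulates: a 4 g bolus with a
#' 1 g/h maintenance infusion started together; serum magnesium is
#' measured 1 h after the start and 1 h after every rate change, and when
#' that measured value is below the target the maintenance rate is raised
#' by 0.25 g/h.  Titration only ever increases the rate; once a check
#' reads at or above target (or the rate cap is reached without a
#' possible increase) no further checks are scheduled.
#'
#' @param bolus_dose bolus dose (g), default 4.
#' @param initial_rate initial maintenance rate (g/h), default 1.
#' @param titration_step rate increment (g/h), default 0.25.
#' @param titration_threshold measured concentration (mmol/L) below which
#'   the rate is raised, default 2.0.
#' @param check_delay delay (h) between a start/rate change and its check
#'   measurement, default 1.
#' @param max_rate cap on the maintenance rate (g/h), default 1.5 — with
#'   the 0.25 g/h step this allows two titration increments, keeping the
#'   time-weighted mean rate in the 1.0-1.5 g/h range typical of
#'   titrated Zuspan treatment.
#' @param extra_sampling additional routine sampling times (h), default
#'   `c(4, 8, 12, 18, 24)`.
#' @param extra_sampling_interval routine sampling interval after the
#'   last `extra_sampling` time (h), default 12.
#' @param max_duration cap on treatment duration (h), default 60.
#' @param bolus_duration bolus administration time (h), default 1/3 h.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(bolus_dose = 4, initial_rate = 1,
                            titration_step = 0.25, titration_threshold = 2.0,
                            check_delay = 1, max_rate = 1.5,
                            extra_sampling = c(4, 8, 12, 18, 24),
                            extra_sampling_interval = 12,
                            max_duration = 60, bolus_duration = 1 / 3) {
  stopifnot(bolus_dose > 0, initial_rate > 0, titration_step > 0,
            titration_threshold >= 0, check_delay > 0,
            max_rate >= initial_rate, all(extra_sampling > 0),
            extra_sampling_interval > 0, max_duration > 0,
            bolus_duration >= 0)
  structure(
    list(bolus_dose = bolus_dose, initial_rate = initial_rate,
         titration_step = titration_step,
         titration_threshold = titration_threshold,
         check_delay = check_delay, max_rate = max_rate,
         extra_sampling = sort(extra_sampling),
         extra_sampling_interval = extra_sampling_interval,
         max_duration = max_duration, bolus_duration = bolus_duration),
    class = "protocol_config"
  )
}

#' Measurement-error model for simulated magnesium assays
#'
#' Combined proportional + additive Gaussian assay error, optional
#' systematic bias terms (used to study bias recovery), and rare spurious
#' high readings emulating pre-analytical errors (e.g. sampling from the
#' infusion arm), drawn uniformly over `outlier_range`.
#'
#' @param prop_cv proportional coefficient of variation, default 0.07.
#' @param add_sd additive SD (mmol/L), default 0.05.
#' @param outlier_prob per-sample probability of a spurious reading,
#'   default 0.01.
#' @param outlier_range range (mmol/L) of spurious readings, default
#'   `c(3.5, 7.5)`.
#' @param bias constant additive bias (mmol/L), default 0.
#' @param bias_weight_slope additive bias per kg body weight
#'   (mmol/L per kg), default 0.
#' @return A list of class `error_model`.
#' @export
error_model <- function(prop_cv = 0.07, add_sd = 0.05, outlier_prob = 0.01,
                        outlier_range = c(3.5, 7.5), bias = 0,
                        bias_weight_slope = 0) {
  stopifnot(prop_cv >= 0, add_sd >= 0, outlier_prob >= 0, outlier_prob <= 1,
            length(outlier_range) == 2L, outlier_range[1] <= outlier_range[2])
  structure(
    list(prop_cv = prop_cv, add_sd = add_sd, outlier_prob = outlier_prob,
         outlier_range = outlier_range, bias = bias,
         bias_weight_slope = bias_weight_slope),
    class = "error_model"
  )
}

#' A noiseless measurement model
#' @return An [error_model()] with every error component zero.
#' @export
zero_error_model <- function() {
  error_model(prop_cv = 0, add_sd = 0, outlier_prob = 0)
}

# corrupt true concentrations with the error model; uses the current RNG
.apply_error <- function(true_conc, weight, error) {
  n <- length(true_conc)
  meas <- true_conc * (1 + stats::rnorm(n, 0, error$prop_cv)) +
    stats::rnorm(n, 0, error$add_sd) +
    error$bias + error$bias_weight_slope * weight
  if (error$outlier_prob > 0) {
    sp <- stats::runif(n) < error$outlier_prob
    if (any(sp)) {
      meas[sp] <- stats::runif(sum(sp), error$outlier_range[1],
                               error$outlier_range[2])
    }
  } else {
    sp <- rep(FALSE, n)
  }
  list(conc = pmax(meas, 0.01), is_outlier = sp)
}

#' Demographic distribution configuration
#'
#' Marginal log-normal distributions parameterized by (first quartile,
#' median, third quartile): `meanlog = log(median)` and `sdlog` solved
#' from the interquartile ratio, `sdlog = log(q3/q1) / (2 z_{0.75})`.
#' Defaults reproduce the quartile summaries of a titrated-Zuspan
#' preeclampsia cohort: weight (73, 84, 95) kg, creatinine (51, 57, 69)
#' umol/L, gestational age (33.1, 35.7, 38.4) weeks and treatment
#' duration (23.7, 29.6, 46.0) h.
#'
#' @param weight,creatinine,gestational_age,duration numeric length-3
#'   vectors `(q1, median, q3)`, strictly increasing.
#' @param copula_rho optional Gaussian-copula correlation between weight
#'   and creatinine, default 0 (independent).
#' @return A list of class `demographics_config`.
#' @export
demographics_config <- function(weight = c(73, 84, 95),
                                creatinine = c(51, 57, 69),
                                gestational_age = c(33.14, 35.71, 38.43),
                                duration = c(23.7, 29.6, 46.0),
                                copula_rho = 0) {
  for (q in list(weight, creatinine, gestational_age, duration)) {
    if (length(q) != 3L || any(diff(q) <= 0) || any(q <= 0)) {
      stop("each quartile triple must be positive and strictly increasing")
    }
  }
  stopifnot(copula_rho >= -1, copula_rho <= 1)
  structure(
    list(weight = weight, creatinine = creatinine,
         gestational_age = gestational_age, duration = duration,
         copula_rho = copula_rho),
    class = "demographics_config"
  )
}

.lognorm_pars <- function(q) {
  c(meanlog = log(q[2]), sdlog = log(q[3] / q[1]) / (2 * stats::qnorm(0.75)))
}

#' Sample subject demographics
#'
#' Draws `n` subjects with log-normal marginals matched to the quartile
#' configuration.  Weight and creatinine may be correlated through a
#' Gaussian copula (`copula_rho`); gestational age and treatment duration
#' are drawn independently.
#'
#' @param n number of subjects.
#' @param config a [demographics_config()].
#' @param seed optional integer; if given, seeds the RNG (otherwise the
#'   current RNG stream is used).
#' @return data.frame with columns `subject_id`, `weight`, `creatinine`,
#'   `gestational_age`, `duration`.
#' @export
#' @examples
#' head(sample_demographics(5, seed = 1))
sample_demographics <- function(n, config = demographics_config(), seed = NULL) {
  stopifnot(n >= 0, inherits(config, "demographics_config"))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) {
    return(data.frame(subject_id = character(), weight = numeric(),
                      creatinine = numeric(), gestational_age = numeric(),
                      duration = numeric()))
  }
  pw <- .lognorm_pars(config$weight)
  pc <- .lognorm_pars(config$creatinine)
  pg <- .lognorm_pars(config$gestational_age)
  pd <- .lognorm_pars(config$duration)
  zw <- stats::rnorm(n)
  zc <- config$copula_rho * zw +
    sqrt(1 - config$copula_rho^2) * stats::rnorm(n)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    weight = exp(pw["meanlog"] + pw["sdlog"] * zw),
    creatinine = exp(pc["meanlog"] + pc["sdlog"] * zc),
    gestational_age = stats::rlnorm(n, pg["meanlog"], pg["sdlog"]),
    duration = stats::rlnorm(n, pd["meanlog"], pd["sdlog"]),
    row.names = NULL
  )
}

#' Simulate one treated case under the titration protocol
#'
#' Closed-loop simulation: the subject's individualized two-compartment
#' profile drives the titration decisions.  At each check time the
#' *measured* (error-corrupted) concentration is compared with the
#' titration threshold; if below it and the rate cap allows, the
#' maintenance rate is raised and a new check is scheduled `check_delay`
#' later.  Routine samples are added at the protocol's extra sampling
#' times.  All observation times are multiples of the 5-minute prediction
#' grid.
#'
#' @param subject one row of [sample_demographics()] (fields `weight`,
#'   `creatinine`, `duration`; optional `gestational_age`).
#' @param protocol a [protocol_config()].
#' @param typical typical-value [pk_params()].
#' @param covmodel a [covariate_model()].
#' @param error an [error_model()].
#' @param seed integer seed for this case's RNG stream.
#' @param case_id identifier, default the subject id.
#' @return A [case_record()].  The observation table carries attributes
#'   `true_conc` (noise-free concentrations) and `is_outlier` (which
#'   readings were replaced by spurious values).
#' @export
simulate_case <- function(subject, protocol, typical, covmodel, error,
                          seed, case_id = subject$subject_id) {
  stopifnot(inherits(protocol, "protocol_config"),
            inherits(typical, "pk_params"),
            inherits(covmodel, "covariate_model"),
            inherits(error, "error_model"))
  set.seed(seed)
  params <- individualize(typical, covmodel, subject$weight, subject$creatinine)
  duration <- min(max(subject$duration, 2 * protocol$check_delay),
                  protocol$max_duration)
  # snap duration to the 5-minute grid for a reproducible schedule
  duration <- round(duration * 12) / 12

  events <- data.frame(
    time = c(0, 0), kind = c("bolus", "rate_change"),
    dose = c(protocol$bolus_dose, NA), rate = c(NA, protocol$initial_rate),
    bolus_duration = c(protocol$bolus_duration, NA)
  )
  rate <- protocol$initial_rate
  check_times <- numeric()
  check_true <- numeric()
  check_meas <- numeric()
  check_outl <- logical()
  next_check <- protocol$check_delay
  while (next_check < duration) {
    sched_now <- dosing_schedule(events, treatment_end = duration)
    true_c <- conc_at(sched_now, params, next_check)
    meas <- .apply_error(true_c, subject$weight, error)
    check_times <- c(check_times, next_check)
    check_true <- c(check_true, true_c)
    check_meas <- c(check_meas, meas$conc)
    check_outl <- c(check_outl, meas$is_outlier)
    # titration decides on the measured (recorded) value
    if (meas$conc < protocol$titration_threshold &&
        rate + protocol$titration_step <= protocol$max_rate + 1e-12) {
      rate <- rate + protocol$titration_step
      events <- rbind(events, data.frame(
        time = next_check, kind = "rate_change", dose = NA_real_,
        rate = rate, bolus_duration = NA_real_))
      next_check <- next_check + protocol$check_delay
    } else {
      break  # at target, or cap reached: no further change, no further check
    }
  }
  events <- rbind(events, data.frame(time = duration, kind = "stop",
                                     dose = NA_real_, rate = 0,
                                     bolus_duration = NA_real_))
  schedule <- dosing_schedule(events, treatment_end = duration)

  extra <- protocol$extra_sampling[protocol$extra_sampling <= duration]
  last_extra <- if (length(protocol$extra_sampling) > 0)
    max(protocol$extra_sampling) else 0
  if (duration > last_extra + protocol$extra_sampling_interval) {
    extra <- c(extra, seq(last_extra + protocol$extra_sampling_interval,
                          duration, by = protocol$extra_sampling_interval))
  }
  extra <- c(extra, duration)  # end-of-treatment sample
  extra <- sort(unique(extra[!extra %in% check_times]))
  true_extra <- conc_at(schedule, params, extra)
  meas_extra <- .apply_error(true_extra, subject$weight, error)
  ord <- order(c(check_times, extra))
  obs <- data.frame(time = c(check_times, extra)[ord],
                    conc = c(check_meas, meas_extra$conc)[ord],
                    aberrant = FALSE)
  rec <- case_record(case_id = case_id, weight = subject$weight,
                     creatinine = subject$creatinine, schedule = schedule,
                     observations = obs,
                     gestational_age = subject$gestational_age %||% NA_real_)
  attr(rec$observations, "true_conc") <- c(check_true, true_extra)[ord]
  attr(rec$observations, "is_outlier") <- c(check_outl, meas_extra$is_outlier)[ord]
  rec
}

#' Simulate a full cohort
#'
#' Draws `n` subjects from the demographic configuration and simulates
#' each case under the titration protocol.  Per-case seeds are derived
#' deterministically from the master seed, so the output is reproducible.
#'
#' @param n cohort size.
#' @param seed master seed (integer).
#' @param protocol a [protocol_config()].
#' @param typical typical-value [pk_params()].
#' @param covmodel a [covariate_model()].
#' @param error an [error_model()].
#' @param demographics a [demographics_config()].
#' @return An `mg_cohort` of `n` valid cases.
#' @export
#' @examples
#' coh <- simulate_cohort(5, seed = 1)
#' coh
simulate_cohort <- function(n, seed, protocol = protocol_config(),
                            typical = default_pk_params(),
                            covmodel = default_covariate_model(),
                            error = error_model(),
                            demographics = demographics_config()) {
  stopifnot(n >= 0)
  set.seed(seed)
  subjects <- sample_demographics(n, demographics)
  if (n == 0L) return(mg_cohort(list()))
  case_seeds <- sample.int(.Machine$integer.max, n)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cases[[i]] <- simulate_case(subjects[i, ], protocol, typical, covmodel,
                                error, seed = case_seeds[i],
                                case_id = sprintf("S%04d", i))
  }
  mg_cohort(cases)
}
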