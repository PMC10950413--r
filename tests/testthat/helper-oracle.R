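# Independent numerical oracle: integrates the two-compartment amount ODEs
#   dA1/dt = r(t) - (k10 + k12) A1 + k21 A2
#   dA2/dt = k12 A1 - k21 A2,   conc = baseline + A1 / V1
# segment-by-segment (constant input within a segment) with deSolve::lsoda
# at tight tolerances.  Boluses must be infusion-style (duration > 0).
ode_profile_oracle <- function(schedule, params, times) {
  segs <- mgpk:::rate_segments(schedule)
  bol <- schedule[schedule$kind == "bolus", , drop = FALSE]
  stopifnot(all(bol$bolus_duration > 0))
  pieces <- data.frame(
    start = c(bol$time, segs$start),
    end = c(bol$time + bol$bolus_duration, segs$end),
    rate = c(bol$dose * params$dose_to_amount / bol$bolus_duration,
             segs$rate * params$dose_to_amount)
  )
  tmax <- max(times)
  brk <- sort(unique(c(0, pieces$start, pieces$end, times)))
  brk <- brk[brk >= 0 & brk <= tmax]
  if (max(brk) < tmax) brk <- c(brk, tmax)

  deriv <- function(t, y, parms) {
    list(c(parms$r - (params$k10 + params$k12) * y[1] + params$k21 * y[2],
           params$k12 * y[1] - params$k21 * y[2]))
  }
  y <- c(A1 = 0, A2 = 0)
  out_t <- 0
  out_a1 <- 0
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    mid <- (a + b) / 2
    r_const <- sum(pieces$rate[pieces$start <= mid & mid < pieces$end])
    sol <- deSolve::lsoda(y, c(a, b), deriv, parms = list(r = r_const),
                          rtol = 1e-11, atol = 1e-13)
    y <- c(A1 = unname(sol[nrow(sol), 2]), A2 = unname(sol[nrow(sol), 3]))
    out_t <- c(out_t, b)
    out_a1 <- c(out_a1, unname(y[1]))
  }
  conc <- vapply(times, function(t) {
    params$baseline + out_a1[which.min(abs(out_t - t))] / params$V1
  }, numeric(1))
  conc
}

# random parameter sets and schedules for property-style tests
rand_params <- function() {
  pk_params(CL = runif(1, 2, 8), V1 = runif(1, 10, 40),
            Q = runif(1, 0.5, 5), V2 = runif(1, 15, 60))
}

rand_schedule <- function(n_changes = sample(1:5, 1), treatment_end = 24) {
  ch_times <- sort(round(runif(n_changes, 0.5, 20), 2))
  zuspan_schedule(
    bolus_dose = runif(1, 2, 6), initial_rate = runif(1, 0.5, 1.5),
    rate_changes = data.frame(time = ch_times,
                              rate = round(runif(n_changes, 0, 2), 2)),
    treatment_end = treatment_end,
    bolus_duration = runif(1, 1 / 6, 1 / 2))
}

# tiny hand-buildable case
make_case <- function(case_id = "C1", weight = 84, creatinine = 57,
                      obs_times = c(1, 4), obs_conc = c(1.4, 1.8),
                      tend = 24) {
  case_record(case_id, weight, creatinine,
              schedule = zuspan_schedule(treatment_end = tend),
              observations = data.frame(time = obs_times, conc = obs_conc))
}
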