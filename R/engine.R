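#' @title Closed-form two-compartment infusion engine
#' @description
#' The drug-attributable concentration is linear in the dosing input, so
#' an arbitrary history of boluses and piecewise-constant maintenance
#' rates is the superposition of elementary responses:
#'
#' * unit bolus (1 mmol instantaneous into the central compartment):
#'   \eqn{G(t) = (A e^{-\alpha t} + B e^{-\beta t}) / V_1} with
#'   \eqn{A = (\alpha - k_{21})/(\alpha - \beta)},
#'   \eqn{B = (k_{21} - \beta)/(\alpha - \beta)};
#' * running unit-rate infusion (1 mmol/h started at 0, still running):
#'   \eqn{F(t) = \int_0^t G(s) ds =
#'     [A (1 - e^{-\alpha t})/\alpha + B (1 - e^{-\beta t})/\beta] / V_1},
#'   with \eqn{F(t) \to 1/CL} as \eqn{t \to \infty};
#' * a rate segment \eqn{r} on \eqn{[t_0, t_1)} contributes
#'   \eqn{r\,[F(t - t_0) - F(t - t_1)]} (the second term switched on only
#'   past \eqn{t_1}), i.e. a stopped segment decays with the biexponential
#'   washout.
#'
#' With `Q = 0` the model degenerates to one compartment and the limits
#' \eqn{G(t) = e^{-k_{10} t} / V_1}, \eqn{F(t) = (1 - e^{-k_{10} t})/CL}
#' are used.  The endogenous baseline is a flat additive constant.
#' @name engine
#' @keywords internal
NULL

# cumulative unit-rate infusion response F(t) (mmol/L per mmol/h), 0 for t < 0
.unit_infusion_cum <- function(t, params) {
  out <- numeric(length(t))
  pos <- t > 0
  if (!any(pos)) return(out)
  tp <- t[pos]
  if (params$Q > 0) {
    hc <- hybrid_constants(params)
    a <- hc[["alpha"]]; b <- hc[["beta"]]
    A <- (a - params$k21) / (a - b)
    B <- (params$k21 - b) / (a - b)
    out[pos] <- (A * (1 - exp(-a * tp)) / a +
                 B * (1 - exp(-b * tp)) / b) / params$V1
  } else {
    out[pos] <- (1 - exp(-params$k10 * tp)) / params$CL
  }
  out
}

# unit instantaneous bolus response G(t) (mmol/L per mmol), 0 for t < 0
.unit_bolus <- function(t, params) {
  out <- numeric(length(t))
  pos <- t >= 0
  if (!any(pos)) return(out)
  tp <- t[pos]
  if (params$Q > 0) {
    hc <- hybrid_constants(params)
    a <- hc[["alpha"]]; b <- hc[["beta"]]
    A <- (a - params$k21) / (a - b)
    B <- (params$k21 - b) / (a - b)
    out[pos] <- (A * exp(-a * tp) + B * exp(-b * tp)) / params$V1
  } else {
    out[pos] <- exp(-params$k10 * tp) / params$V1
  }
  out
}

#' Concentration contribution of a running constant infusion
#'
#' Central-compartment concentration at `t_since_start` hours of a
#' constant infusion of elemental magnesium started at time 0 and still
#' running.  Monotone nondecreasing in `t`, with limit `rate / CL`.
#'
#' @param rate infusion rate in mmol/h (elemental Mg), >= 0.
#' @param t_since_start time since infusion start (h), >= 0; vectorized.
#' @param params a [pk_params()] object.
#' @return Drug-attributable concentration (mmol/L), excluding baseline.
#' @export
#' @examples
#' p <- default_pk_params()
#' infusion_response(4.06, c(1, 24, 1000), p)
infusion_response <- function(rate, t_since_start, params) {
  stopifnot(inherits(params, "pk_params"),
            is.numeric(rate), length(rate) == 1L, rate >= 0)
  if (any(t_since_start < 0)) stop("t_since_start must be >= 0")
  rate * .unit_infusion_cum(t_since_start, params)
}

#' Exact concentration at arbitrary times for a dosing schedule
#'
#' Evaluates the closed-form superposition (baseline + boluses +
#' maintenance segments) at the requested times, without a grid.
#'
#' @param schedule a [dosing_schedule()].
#' @param params a [pk_params()] object.
#' @param times times (h since first bolus), >= 0; vectorized.
#' @return Total serum magnesium (mmol/L) at `times`.
#' @export
conc_at <- function(schedule, params, times) {
  stopifnot(inherits(schedule, "dosing_schedule"), inherits(params, "pk_params"))
  if (any(times < 0)) stop("times must be >= 0")
  conc <- rep(params$baseline, length(times))
  bol <- schedule[schedule$kind == "bolus", , drop = FALSE]
  for (i in seq_len(nrow(bol))) {
    amt <- bol$dose[i] * params$dose_to_amount  # mmol
    dur <- bol$bolus_duration[i]
    if (dur > 0) {
      r <- amt / dur  # mmol/h over [time, time + dur)
      conc <- conc + r * (.unit_infusion_cum(times - bol$time[i], params) -
                          .unit_infusion_cum(times - bol$time[i] - dur, params))
    } else {
      conc <- conc + amt * .unit_bolus(times - bol$time[i], params)
    }
  }
  seg <- rate_segments(schedule)
  for (i in seq_len(nrow(seg))) {
    r <- seg$rate[i] * params$dose_to_amount  # mmol/h
    if (r == 0) next
    conc <- conc + r * (.unit_infusion_cum(times - seg$start[i], params) -
                        .unit_infusion_cum(times - seg$end[i], params))
  }
  conc
}

#' Predict a concentration profile on a fixed-resolution grid
#'
#' Individual concentration table: total serum magnesium on a uniform
#' grid from 0 to `horizon` at `resolution` spacing (default 5 minutes),
#' taking bolus doses and every maintenance-rate change into account.
#' Deterministic for fixed inputs.
#'
#' @param schedule a [dosing_schedule()] (normalized: first bolus at 0).
#' @param params a [pk_params()] object.
#' @param resolution grid spacing (h), default `1/12` (5 min).
#' @param horizon last grid time (h); may extend past `treatment_end` to
#'   cover post-infusion washout.  Default `treatment_end(schedule)`.
#' @return An object of class `concentration_profile`: a data.frame with
#'   columns `time` (h) and `conc` (mmol/L), attributes `resolution` and
#'   `baseline`.
#' @export
#' @examples
#' prof <- predict_profile(zuspan_schedule(treatment_end = 24),
#'                         default_pk_params(), horizon = 30)
#' head(prof)
predict_profile <- function(schedule, params, resolution = 1 / 12,
                            horizon = treatment_end(schedule)) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0,
            is.numeric(horizon), length(horizon) == 1L, horizon >= 0)
  # tolerant floor so a horizon sitting exactly on the grid keeps its point
  grid <- seq(0L, floor(horizon / resolution + 1e-9)) * resolution
  conc <- conc_at(schedule, params, grid)
  structure(
    data.frame(time = grid, conc = conc),
    class = c("concentration_profile", "data.frame"),
    resolution = resolution, baseline = params$baseline
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf(
    "<concentration_profile> %d points, 0-%g h at %.4g h resolution; peak %.3g mmol/L\n",
    nrow(x), max(x$time), attr(x, "resolution"), max(x$conc)))
  invisible(x)
}

#' First grid time strictly above a threshold
#'
#' Evaluated on the profile grid (no interpolation) for determinism.
#'
#' @param profile a [predict_profile()] result.
#' @param threshold concentration threshold (mmol/L).
#' @return First grid time (h) with `conc > threshold`, or `NA_real_` if
#'   the threshold is never exceeded on the grid.
#' @export
time_to_threshold <- function(profile, threshold) {
  stopifnot(inherits(profile, "concentration_profile"),
            is.numeric(threshold), length(threshold) == 1L)
  idx <- which(profile$conc > threshold)
  if (length(idx) == 0L) NA_real_ else profile$time[idx[1L]]
}
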