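#' Treatment-period bin of an observation time
#'
#' Half-open bins partitioning the first 60 h of treatment: early
#' `[0, 4)`, intermediate `[4, 17)`, late `[17, 25)` and extended
#' `[25, 60]`; times beyond 60 h get `NA`.
#'
#' @param time hours since first bolus; vectorized.
#' @return Factor with levels early, intermediate, late, extended.
#' @export
period_bin <- function(time) {
  lv <- c("early", "intermediate", "late", "extended")
  out <- rep(NA_character_, length(time))
  out[time >= 0 & time < 4] <- "early"
  out[time >= 4 & time < 17] <- "intermediate"
  out[time >= 17 & time < 25] <- "late"
  out[time >= 25 & time <= 60] <- "extended"
  factor(out, levels = lv)
}

#' Time-match observations to a predicted profile
#'
#' Pairs each non-aberrant observation with the nearest grid point of the
#' predicted profile (offset at most half the grid resolution).
#' Observations beyond the profile horizon are dropped with a warning.
#'
#' @param profile a [predict_profile()] result.
#' @param observations observation data.frame (`time`, `conc`,
#'   optional `aberrant`).
#' @return data.frame of matched pairs: `time` (observation time, h),
#'   `pred_time` (matched grid time), `measured`, `predicted`,
#'   `error = measured - predicted` (mmol/L; negative means the model
#'   overestimates), `period` (treatment-period bin of `time`).
#' @export
match_predictions <- function(profile, observations) {
  stopifnot(inherits(profile, "concentration_profile"))
  obs <- as.data.frame(observations)
  if (is.null(obs$aberrant)) obs$aberrant <- FALSE
  obs <- obs[!obs$aberrant, , drop = FALSE]
  res <- attr(profile, "resolution")
  horizon <- profile$time[nrow(profile)]
  beyond <- obs$time > horizon + res / 2
  if (any(beyond)) {
    warning(sprintf("dropped %d observation(s) beyond the profile horizon",
                    sum(beyond)))
    obs <- obs[!beyond, , drop = FALSE]
  }
  if (nrow(obs) == 0L) {
    return(data.frame(time = numeric(), pred_time = numeric(),
                      measured = numeric(), predicted = numeric(),
                      error = numeric(),
                      period = period_bin(numeric())))
  }
  idx <- pmin(pmax(round(obs$time / res), 0L) + 1L, nrow(profile))
  data.frame(
    time = obs$time,
    pred_time = profile$time[idx],
    measured = obs$conc,
    predicted = profile$conc[idx],
    error = obs$conc - profile$conc[idx],
    period = period_bin(obs$time)
  )
}

#' Time-matched prediction errors for a whole cohort
#'
#' For each case: individualize the typical parameters with the case
#' covariates, predict the concentration profile over the case's dosing
#' history, optionally screen observations for aberrant values
#' ([flag_aberrant()]), and time-match.  Case covariates are carried on
#' each pair for the bias regressions.
#'
#' @param cohort an `mg_cohort`.
#' @param typical typical-value [pk_params()].
#' @param covmodel a [covariate_model()].
#' @param resolution prediction grid spacing (h), default 5 min.
#' @param flag logical: run [flag_aberrant()] before matching (default
#'   TRUE, mirroring the omission of erroneous spikes from the
#'   validation).
#' @param ... passed to [flag_aberrant()].
#' @return data.frame of pairs with columns of [match_predictions()] plus
#'   `case_id`, `weight`, `creatinine`, `duration` (treatment duration,
#'   h).
#' @export
validate_predictions <- function(cohort, typical = default_pk_params(),
                                 covmodel = default_covariate_model(),
                                 resolution = 1 / 12, flag = TRUE, ...) {
  stopifnot(inherits(cohort, "mg_cohort"))
  out <- lapply(unname(cohort$cases), function(cs) {
    params <- individualize(typical, covmodel, cs$weight, cs$creatinine)
    obs <- if (flag) flag_aberrant(cs$observations, ...) else cs$observations
    horizon <- max(treatment_end(cs$schedule), max(obs$time))
    prof <- predict_profile(cs$schedule, params, resolution = resolution,
                            horizon = horizon)
    pairs <- match_predictions(prof, obs)
    if (nrow(pairs) == 0L) return(NULL)
    cbind(case_id = cs$case_id, pairs, weight = cs$weight,
          creatinine = cs$creatinine,
          duration = treatment_end(cs$schedule))
  })
  do.call(rbind, out)
}

#' Mean prediction error with confidence interval
#'
#' Sample mean of the time-matched errors (measured minus predicted) with
#' a Student-t confidence interval.  Negative values mean the model
#' overestimates the measured concentration.  By default all pairs are
#' pooled; `cluster = TRUE` first averages within case and computes the
#' interval over case means, acknowledging within-case correlation.
#'
#' @param pairs pair data.frame from [validate_predictions()] or
#'   [match_predictions()] (needs `case_id` when `cluster = TRUE`).
#' @param conf confidence level, default 0.95.
#' @param cluster logical, see above.
#' @return list with `mean`, `ci` (length-2), `se`, `n` (number of units
#'   the interval is computed over) and `df`.
#' @export
mean_prediction_error <- function(pairs, conf = 0.95, cluster = FALSE) {
  if (cluster) {
    stopifnot("case_id" %in% names(pairs))
    e <- tapply(pairs$error, pairs$case_id, mean)
    e <- as.numeric(e)
  } else {
    e <- pairs$error
  }
  n <- length(e)
  if (n < 2L) stop("need at least 2 prediction-error pairs")
  m <- mean(e)
  se <- stats::sd(e) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  list(mean = m, ci = c(m - tq * se, m + tq * se), se = se, n = n, df = n - 1)
}

#' Bias regression of prediction error on a covariate
#'
#' Ordinary least squares of the prediction error on one of body weight,
#' serum creatinine or treatment duration, with a two-sided t-test on the
#' slope.  A flat (zero-slope) relation indicates no covariate bias.
#'
#' @param pairs pair data.frame from [validate_predictions()] (must carry
#'   the covariate column).
#' @param covariate one of "weight", "creatinine", "duration".
#' @return list with `slope`, `se`, `p`, `intercept`, `n`.
#' @export
bias_regression <- function(pairs,
                            covariate = c("weight", "creatinine", "duration")) {
  covariate <- match.arg(covariate)
  stopifnot(covariate %in% names(pairs), nrow(pairs) >= 3L)
  fit <- stats::lm(pairs$error ~ pairs[[covariate]])
  cf <- summary(fit)$coefficients
  slope <- unname(cf[2L, 1L])
  se <- unname(cf[2L, 2L])
  p <- unname(cf[2L, 4L])
  if (is.nan(p)) p <- if (abs(slope) > 0) 0 else NA_real_
  list(slope = slope, se = se, p = p,
       intercept = unname(cf[1L, 1L]), n = nrow(pairs))
}

#' Calibration table: mean measured concentration per predicted bin
#'
#' Bins the pairs into `n_bins` equal-width bins over the range of
#' predicted concentrations and reports the mean measured concentration
#' per bin; for a well-calibrated model the bin means lie on the
#' identity line.  Empty bins are omitted.
#'
#' @param pairs pair data.frame.
#' @param n_bins number of equal-width bins, default 10.
#' @return data.frame with `midpoint` (predicted-bin midpoint, mmol/L),
#'   `mean_measured` (mmol/L) and `n`.
#' @export
calibration_table <- function(pairs, n_bins = 10) {
  stopifnot(nrow(pairs) >= 1L, n_bins >= 1L)
  lo <- min(pairs$predicted)
  hi <- max(pairs$predicted)
  if (hi == lo) {
    return(data.frame(midpoint = lo, mean_measured = mean(pairs$measured),
                      n = nrow(pairs)))
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(findInterval(pairs$predicted, breaks), n_bins)
  mid <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  agg <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    data.frame(midpoint = mid[b], mean_measured = mean(pairs$measured[sel]),
               n = sum(sel))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Treatment-period summary and adjacent-bin comparisons
#'
#' Per period bin: number of observations, mean maintenance rate in force
#' at the sampling times, and mean measured concentration.  Adjacent
#' non-empty bins are compared by Welch two-sample t-tests on both
#' quantities.
#'
#' @param cohort the `mg_cohort` the pairs came from (for the rate in
#'   force at each sampling time).
#' @param pairs pair data.frame from [validate_predictions()].
#' @return list with `summary` (data.frame `period`, `n`, `mean_rate`,
#'   `mean_measured`) and `comparisons` (data.frame `from`, `to`,
#'   `rate_diff`, `rate_p`, `conc_diff`, `conc_p`).
#' @export
period_summary <- function(cohort, pairs) {
  stopifnot(inherits(cohort, "mg_cohort"), all(c("case_id", "time", "measured",
                                                 "period") %in% names(pairs)))
  pairs$rate <- mapply(function(cid, tt) rate_at(cohort$cases[[cid]]$schedule, tt),
                       pairs$case_id, pairs$time)
  lv <- levels(pairs$period)
  summary_df <- do.call(rbind, lapply(lv, function(b) {
    sel <- !is.na(pairs$period) & pairs$period == b
    data.frame(period = b, n = sum(sel),
               mean_rate = if (any(sel)) mean(pairs$rate[sel]) else NA_real_,
               mean_measured = if (any(sel)) mean(pairs$measured[sel]) else NA_real_)
  }))
  nonempty <- summary_df$period[summary_df$n > 0L]
  comparisons <- NULL
  if (length(nonempty) >= 2L) {
    comparisons <- do.call(rbind, lapply(seq_len(length(nonempty) - 1L),
                                         function(i) {
      a <- pairs[!is.na(pairs$period) & pairs$period == nonempty[i], ]
      b <- pairs[!is.na(pairs$period) & pairs$period == nonempty[i + 1L], ]
      welch <- function(x, y) {
        if (length(x) < 2L || length(y) < 2L ||
            (stats::sd(x) == 0 && stats::sd(y) == 0)) {
          return(NA_real_)
        }
        stats::t.test(y, x)$p.value
      }
      data.frame(from = nonempty[i], to = nonempty[i + 1L],
                 rate_diff = mean(b$rate) - mean(a$rate),
                 rate_p = welch(a$rate, b$rate),
                 conc_diff = mean(b$measured) - mean(a$measured),
                 conc_p = welch(a$measured, b$measured))
    }))
  }
  list(summary = summary_df, comparisons = comparisons)
}

#' Flag aberrant (spurious) high measurements
#'
#' Screens an observation series for spurious spikes: observation `i` is
#' flagged when its concentration exceeds `high_threshold`, it sits more
#' than `rebound_tol` above the last preceding unflagged value (it is
#' unexpectedly high), and a later observation within `lookahead` hours
#' returns to within `rebound_tol` of that preceding value (subsequent
#' levels confirm the spike was not real).  The last observation of a
#' series is never auto-flagged, and neither is a high first observation
#' (no reference level); such unconfirmed exceedances are listed in the
#' `manual_review` attribute.
#'
#' @param observations observation data.frame (`time`, `conc`, optional
#'   existing `aberrant` flags, which are kept).
#' @param high_threshold spike threshold (mmol/L), default 3.5.
#' @param lookahead confirmation window (h), default 6.
#' @param rebound_tol return tolerance (mmol/L), default 0.5.
#' @return The observation data.frame with updated `aberrant` flags and
#'   an integer attribute `manual_review` (row indices of unconfirmed
#'   exceedances).
#' @export
#' @examples
#' flag_aberrant(data.frame(time = 1:3, conc = c(1.8, 7.28, 1.9)))
flag_aberrant <- function(observations, high_threshold = 3.5, lookahead = 6,
                          rebound_tol = 0.5) {
  obs <- as.data.frame(observations)
  if (is.null(obs$aberrant)) obs$aberrant <- FALSE
  n <- nrow(obs)
  manual <- integer()
  for (i in seq_len(n)) {
    if (obs$aberrant[i] || obs$conc[i] <= high_threshold) next
    prev <- which(!obs$aberrant[seq_len(i - 1L)])
    if (i == n || length(prev) == 0L) {
      manual <- c(manual, i)
      next
    }
    ref <- obs$conc[max(prev)]
    is_spike <- obs$conc[i] - ref > rebound_tol
    later <- which(obs$time > obs$time[i] &
                   obs$time <= obs$time[i] + lookahead)
    rebounds <- length(later) > 0L &&
      any(abs(obs$conc[later] - ref) <= rebound_tol)
    if (is_spike && rebounds) {
      obs$aberrant[i] <- TRUE
    } else {
      manual <- c(manual, i)
    }
  }
  attr(obs, "manual_review") <- manual
  obs
}

#' Toxicity screening: review list of high measurements
#'
#' Lists every measurement strictly above the toxicity threshold across
#' the cohort (flagged or not), noting whether a later measurement of the
#' same case returned to or below the threshold (resolved by renewed
#' sampling).
#'
#' @param cohort an `mg_cohort`.
#' @param threshold toxicity threshold (mmol/L), default 3.5 (loss of
#'   patellar reflex).
#' @return data.frame `case_id`, `time`, `conc`, `aberrant`,
#'   `resolved_by_resample` (zero rows when no exceedance).
#' @export
screen_toxicity <- function(cohort, threshold = 3.5) {
  stopifnot(inherits(cohort, "mg_cohort"))
  rows <- lapply(unname(cohort$cases), function(cs) {
    obs <- cs$observations
    hi <- which(obs$conc > threshold)
    if (length(hi) == 0L) return(NULL)
    data.frame(case_id = cs$case_id, time = obs$time[hi], conc = obs$conc[hi],
               aberrant = obs$aberrant[hi],
               resolved_by_resample = vapply(hi, function(i) {
                 any(obs$time > obs$time[i] & obs$conc <= threshold)
               }, logical(1)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(case_id = character(), time = numeric(),
                      conc = numeric(), aberrant = logical(),
                      resolved_by_resample = logical())
  }
  out
}
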