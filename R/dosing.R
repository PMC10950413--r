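#' Dosing schedule: ordered bolus and maintenance-rate events
#'
#' A dosing history on a time-since-first-bolus axis.  Events are either a
#' `bolus` (labelled dose in g, given as a short infusion of
#' `bolus_duration` hours), a `rate_change` (new maintenance rate in g/h,
#' piecewise constant until the next rate event) or a `stop` (maintenance
#' rate set to 0).  Events are sorted by time with boluses before rate
#' events at equal times.
#'
#' @param events a data.frame with columns `time` (h), `kind`
#'   ("bolus", "rate_change" or "stop"), `dose` (g, boluses only, NA
#'   otherwise), `rate` (g/h, rate changes only, NA otherwise) and
#'   optionally `bolus_duration` (h; defaults to 1/3 h = 20 min for
#'   boluses, 0 means an instantaneous bolus).
#' @param treatment_end end of treatment (h); maintenance infusion stops
#'   here.  Must be at least the last event time.
#' @param normalized logical; assert that times are already on the
#'   since-first-bolus axis (first bolus at 0).  Default TRUE; schedules
#'   read from clock-stamped files are normalized by [normalize_times()].
#' @return An object of class `dosing_schedule`: the sorted event
#'   data.frame with attribute `treatment_end`.
#' @seealso [zuspan_schedule()], [predict_profile()], [weighted_mean_rate()]
#' @export
#' @examples
#' dosing_schedule(data.frame(
#'   time = c(0, 0, 5), kind = c("bolus", "rate_change", "rate_change"),
#'   dose = c(4, NA, NA), rate = c(NA, 1, 1.25)), treatment_end = 30)
dosing_schedule <- function(events, treatment_end, normalized = TRUE) {
  stopifnot(is.data.frame(events), nrow(events) >= 1L,
            all(c("time", "kind", "dose", "rate") %in% names(events)))
  ev <- as.data.frame(events)
  if (is.null(ev$bolus_duration)) ev$bolus_duration <- NA_real_
  ev <- ev[, c("time", "kind", "dose", "rate", "bolus_duration")]
  stopifnot(is.numeric(ev$time), all(is.finite(ev$time)),
            all(ev$kind %in% c("bolus", "rate_change", "stop")))
  if (any(ev$time < 0)) stop("event times must be >= 0 (time since first bolus)")
  is_bolus <- ev$kind == "bolus"
  if (!any(is_bolus)) stop("schedule has no bolus event")
  if (any(is_bolus & (is.na(ev$dose) | ev$dose <= 0))) {
    stop("bolus events need dose > 0 (g)")
  }
  ev$bolus_duration[is_bolus & is.na(ev$bolus_duration)] <- 1 / 3
  if (any(is_bolus & ev$bolus_duration < 0)) stop("bolus_duration must be >= 0")
  is_rate <- ev$kind == "rate_change"
  if (any(is_rate & (is.na(ev$rate) | ev$rate < 0))) {
    stop("rate_change events need rate >= 0 (g/h)")
  }
  ev$rate[ev$kind == "stop"] <- 0
  ev$dose[!is_bolus] <- NA_real_
  ev$rate[is_bolus] <- NA_real_
  ev$bolus_duration[!is_bolus] <- NA_real_
  # deterministic order: time, then bolus before rate events
  ord <- order(ev$time, match(ev$kind, c("bolus", "rate_change", "stop")))
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  if (normalized && !(ev$kind[1L] == "bolus" && ev$time[1L] == 0)) {
    stop("schedule not normalized: first event must be a bolus at time 0 ",
         "(run normalize_times() first)")
  }
  stopifnot(is.numeric(treatment_end), length(treatment_end) == 1L,
            is.finite(treatment_end))
  if (treatment_end < max(ev$time)) {
    stop("treatment_end must be >= the last event time")
  }
  # duplicated rate events at one time are ambiguous
  rt <- ev$time[ev$kind != "bolus"]
  if (anyDuplicated(rt)) stop("multiple rate events at the same time")
  structure(ev, class = c("dosing_schedule", "data.frame"),
            treatment_end = treatment_end)
}

#' @export
print.dosing_schedule <- function(x, ...) {
  cat(sprintf("<dosing_schedule> %d events, treatment_end = %g h\n",
              nrow(x), attr(x, "treatment_end")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Treatment end of a dosing schedule
#' @param schedule a [dosing_schedule()].
#' @return treatment end (h).
#' @export
treatment_end <- function(schedule) {
  stopifnot(inherits(schedule, "dosing_schedule"))
  attr(schedule, "treatment_end")
}

#' Guideline (Zuspan) schedule constructor
#'
#' Convenience constructor for the guideline regimen: a bolus at time 0
#' followed by a maintenance infusion started at 0, with optional later
#' rate changes.
#'
#' @param bolus_dose bolus dose (g), default 4.
#' @param initial_rate initial maintenance rate (g/h), default 1.
#' @param rate_changes optional data.frame with columns `time` (h) and
#'   `rate` (g/h) for later titration steps.
#' @param treatment_end end of treatment (h).
#' @param bolus_duration bolus administration time (h), default 20 min.
#' @return A [dosing_schedule()].
#' @export
zuspan_schedule <- function(bolus_dose = 4, initial_rate = 1,
                            rate_changes = NULL, treatment_end = 24,
                            bolus_duration = 1 / 3) {
  ev <- data.frame(
    time = c(0, 0), kind = c("bolus", "rate_change"),
    dose = c(bolus_dose, NA), rate = c(NA, initial_rate),
    bolus_duration = c(bolus_duration, NA)
  )
  if (!is.null(rate_changes) && nrow(rate_changes) > 0L) {
    ev <- rbind(ev, data.frame(
      time = rate_changes$time, kind = "rate_change",
      dose = NA_real_, rate = rate_changes$rate, bolus_duration = NA_real_
    ))
  }
  dosing_schedule(ev, treatment_end = treatment_end)
}

#' Piecewise-constant maintenance segments of a schedule
#'
#' Internal helper: expands the rate events of a schedule into closed
#' segments `[start, end)` with a constant rate, from the first rate event
#' to `treatment_end`.  The rate is 0 before the first rate event.
#'
#' @param schedule a [dosing_schedule()].
#' @return data.frame with columns `start`, `end` (h) and `rate` (g/h).
#' @keywords internal
rate_segments <- function(schedule) {
  stopifnot(inherits(schedule, "dosing_schedule"))
  tend <- attr(schedule, "treatment_end")
  rt <- schedule[schedule$kind != "bolus", , drop = FALSE]
  if (nrow(rt) == 0L) {
    return(data.frame(start = numeric(), end = numeric(), rate = numeric()))
  }
  seg <- data.frame(
    start = rt$time,
    end = c(rt$time[-1L], tend),
    rate = rt$rate
  )
  seg[seg$end > seg$start, , drop = FALSE]
}

#' Time-weighted mean maintenance infusion rate
#'
#' The time-weighted average maintenance rate from the start of
#' maintenance treatment to the end of treatment; bolus doses are
#' excluded.
#'
#' @param schedule a [dosing_schedule()].
#' @return Weighted mean rate (g/h); `NA` if the schedule has no
#'   maintenance segment of positive length.
#' @export
#' @examples
#' s <- zuspan_schedule(rate_changes = data.frame(time = 10, rate = 1.5),
#'                      treatment_end = 20)
#' weighted_mean_rate(s)  # 1.25
weighted_mean_rate <- function(schedule) {
  seg <- rate_segments(schedule)
  dur <- seg$end - seg$start
  if (sum(dur) <= 0) return(NA_real_)
  sum(seg$rate * dur) / sum(dur)
}

#' Maintenance rate in force at given times
#'
#' @param schedule a [dosing_schedule()].
#' @param times times (h since first bolus).
#' @return Numeric vector of rates (g/h); 0 before maintenance start and
#'   after `treatment_end`.
#' @export
rate_at <- function(schedule, times) {
  seg <- rate_segments(schedule)
  out <- numeric(length(times))
  for (i in seq_len(nrow(seg))) {
    sel <- times >= seg$start[i] & times < seg$end[i]
    out[sel] <- seg$rate[i]
  }
  # a sample drawn at the stop instant carries the rate running until then
  if (nrow(seg) > 0L) {
    out[times == seg$end[nrow(seg)]] <- seg$rate[nrow(seg)]
  }
  out
}
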