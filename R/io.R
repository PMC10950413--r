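#' A single treatment case: covariates, dosing history, observations
#'
#' @param case_id character scalar identifier.
#' @param weight body weight (kg), > 0.
#' @param creatinine serum creatinine (umol/L), > 0.
#' @param schedule a [dosing_schedule()] on the since-first-bolus axis.
#' @param observations data.frame with columns `time` (h since first
#'   bolus, strictly increasing), `conc` (mmol/L, > 0) and optionally
#'   `aberrant` (logical flag, default `FALSE`).  At least two
#'   observations are required.
#' @param gestational_age gestational age at treatment start (weeks,
#'   decimal), optional.
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, weight, creatinine, schedule, observations,
                        gestational_age = NA_real_) {
  obs <- as.data.frame(observations)
  if (is.null(obs$aberrant)) obs$aberrant <- FALSE
  obs <- obs[, c("time", "conc", "aberrant")]
  rec <- structure(
    list(case_id = as.character(case_id), weight = weight,
         creatinine = creatinine, gestational_age = gestational_age,
         schedule = schedule, observations = obs),
    class = "case_record"
  )
  reasons <- validate_case(rec)
  if (length(reasons) > 0L) {
    stop(sprintf("invalid case '%s': %s", case_id,
                 paste(reasons, collapse = "; ")))
  }
  rec
}

#' Validate a case record against the cohort inclusion invariants
#'
#' Checks mirror the study-population exclusion flow: a recent creatinine
#' and body weight must be present and positive, the start of treatment
#' (first bolus) must be well defined, and at least two magnesium
#' measurements must exist with strictly increasing times and positive
#' concentrations.
#'
#' @param rec a `case_record` (or a bare list with the same fields).
#' @return Character vector of rejection reasons; empty if the case is
#'   valid.
#' @export
validate_case <- function(rec) {
  reasons <- character()
  if (is.null(rec$creatinine) || !is.numeric(rec$creatinine) ||
      length(rec$creatinine) != 1L || is.na(rec$creatinine) ||
      rec$creatinine <= 0) {
    reasons <- c(reasons, "no recent creatinine measurement")
  }
  if (is.null(rec$weight) || !is.numeric(rec$weight) ||
      length(rec$weight) != 1L || is.na(rec$weight) || rec$weight <= 0) {
    reasons <- c(reasons, "no recent body weight measurement")
  }
  sched_ok <- inherits(rec$schedule, "dosing_schedule") &&
    any(rec$schedule$kind == "bolus")
  if (!sched_ok) {
    reasons <- c(reasons, "no well-defined start of treatment")
  }
  obs <- rec$observations
  if (is.null(obs) || nrow(obs) < 2L) {
    reasons <- c(reasons, "only one measurement of magnesium")
  } else {
    if (any(diff(obs$time) <= 0)) {
      reasons <- c(reasons, "observation times not strictly increasing")
    }
    if (any(!is.finite(obs$conc) | obs$conc <= 0)) {
      reasons <- c(reasons, "non-positive magnesium concentration")
    }
    if (any(obs$time < 0)) {
      reasons <- c(reasons, "observation before first bolus")
    }
  }
  reasons
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf(
    "<case_record> %s: %g kg, creatinine %g umol/L, %d dosing events, %d observations\n",
    x$case_id, x$weight, x$creatinine, nrow(x$schedule), nrow(x$observations)))
  invisible(x)
}

#' Construct a cohort from case records
#'
#' @param cases list of [case_record()] objects.
#' @param rejected data.frame of rejected cases with columns `case_id`
#'   and `reason` (may have zero rows).
#' @return An object of class `mg_cohort`.
#' @export
mg_cohort <- function(cases, rejected = NULL) {
  stopifnot(is.list(cases), all(vapply(cases, inherits, logical(1), "case_record")))
  if (is.null(rejected)) {
    rejected <- data.frame(case_id = character(), reason = character())
  }
  names(cases) <- vapply(cases, function(cs) cs$case_id, character(1))
  if (anyDuplicated(names(cases))) stop("duplicated case_id in cohort")
  structure(list(cases = cases, rejected = rejected), class = "mg_cohort")
}

#' @export
print.mg_cohort <- function(x, ...) {
  cat(sprintf("<mg_cohort> %d cases (%d rejected), %d observations\n",
              length(x$cases), nrow(x$rejected),
              sum(vapply(x$cases, function(cs) nrow(cs$observations), integer(1)))))
  invisible(x)
}

#' Covariates of a cohort as a data.frame
#' @param cohort an `mg_cohort`.
#' @return data.frame with one row per case: `case_id`, `weight`,
#'   `creatinine`, `gestational_age`.
#' @export
cohort_covariates <- function(cohort) {
  stopifnot(inherits(cohort, "mg_cohort"))
  do.call(rbind, lapply(unname(cohort$cases), function(cs) {
    data.frame(case_id = cs$case_id, weight = cs$weight,
               creatinine = cs$creatinine,
               gestational_age = cs$gestational_age)
  }))
}

.parse_times <- function(x, mode, file, rows) {
  if (mode == "hours") {
    tt <- suppressWarnings(as.numeric(x))
  } else {
    ts <- as.POSIXct(x, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    tt <- as.numeric(ts) / 3600
  }
  bad <- which(is.na(tt))
  if (length(bad) > 0L) {
    stop(sprintf("%s: malformed time at row %d", file, rows[bad[1L]]))
  }
  tt
}

.read_csv_cols <- function(file, required) {
  if (!file.exists(file)) stop("file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Read a cohort from three tidy CSV files
#'
#' Reads covariates, dosing events and magnesium observations, assembles
#' one record per `case_id`, normalizes all times to time since first
#' bolus, and partitions cases into accepted records and a rejection list
#' with reasons (the study-population exclusion flow).
#'
#' File contracts (UTF-8, header required):
#' * covariates: `case_id, weight_kg, creatinine_umol_L`
#'   (optional `gestational_age_weeks`)
#' * dosing: `case_id, time, kind, dose_g, rate_g_per_h`
#'   (optional `bolus_duration_h`); `kind` in bolus / rate_change / stop;
#'   a trailing `stop` event marks the end of treatment
#' * observations: `case_id, time, conc_mmol_L` (optional `aberrant`)
#'
#' @param dosing_file,observation_file,covariate_file CSV paths.
#' @param time_mode "hours" (numeric hours) or "clock" (ISO 8601
#'   timestamps, converted to hours).
#' @return An `mg_cohort` with accepted `cases` and a `rejected`
#'   data.frame (`case_id`, `reason`).
#' @export
read_cohort <- function(dosing_file, observation_file, covariate_file,
                        time_mode = c("hours", "clock")) {
  time_mode <- match.arg(time_mode)
  cov <- .read_csv_cols(covariate_file,
                        c("case_id", "weight_kg", "creatinine_umol_L"))
  dos <- .read_csv_cols(dosing_file,
                        c("case_id", "time", "kind", "dose_g", "rate_g_per_h"))
  obs <- .read_csv_cols(observation_file, c("case_id", "time", "conc_mmol_L"))

  cov$case_id <- as.character(cov$case_id)
  dos$case_id <- as.character(dos$case_id)
  obs$case_id <- as.character(obs$case_id)
  unknown <- setdiff(c(dos$case_id, obs$case_id), cov$case_id)
  if (length(unknown) > 0L) {
    stop("case_id without covariate row: ", paste(unique(unknown), collapse = ", "))
  }
  dos$time <- .parse_times(dos$time, time_mode, dosing_file, seq_len(nrow(dos)) + 1L)
  obs$time <- .parse_times(obs$time, time_mode, observation_file,
                           seq_len(nrow(obs)) + 1L)
  bad_conc <- which(!is.finite(suppressWarnings(as.numeric(obs$conc_mmol_L))))
  if (length(bad_conc) > 0L) {
    stop(sprintf("%s: malformed concentration at row %d", observation_file,
                 bad_conc[1L] + 1L))
  }
  if (is.null(dos$bolus_duration_h)) dos$bolus_duration_h <- NA_real_
  if (is.null(obs$aberrant)) obs$aberrant <- FALSE
  if (is.null(cov$gestational_age_weeks)) cov$gestational_age_weeks <- NA_real_

  cases <- list()
  rejected <- data.frame(case_id = character(), reason = character())
  for (i in seq_len(nrow(cov))) {
    cid <- cov$case_id[i]
    d <- dos[dos$case_id == cid, , drop = FALSE]
    o <- obs[obs$case_id == cid, , drop = FALSE]
    o <- o[order(o$time), , drop = FALSE]
    reasons <- character()
    sched <- NULL
    if (!any(d$kind == "bolus")) {
      reasons <- c(reasons, "no well-defined start of treatment")
    } else {
      ev <- data.frame(time = d$time, kind = d$kind, dose = d$dose_g,
                       rate = d$rate_g_per_h,
                       bolus_duration = d$bolus_duration_h)
      sched <- tryCatch(
        dosing_schedule(ev, treatment_end = max(ev$time), normalized = FALSE),
        error = function(e) {
          reasons <<- c(reasons, conditionMessage(e))
          NULL
        })
    }
    rec <- list(case_id = cid,
                weight = suppressWarnings(as.numeric(cov$weight_kg[i])),
                creatinine = suppressWarnings(as.numeric(cov$creatinine_umol_L[i])),
                gestational_age = suppressWarnings(
                  as.numeric(cov$gestational_age_weeks[i])),
                schedule = sched,
                observations = data.frame(
                  time = o$time, conc = as.numeric(o$conc_mmol_L),
                  aberrant = as.logical(o$aberrant)))
    rec <- if (is.null(sched)) rec else normalize_times_raw(rec)
    reasons <- c(reasons, validate_case(rec))
    if (length(reasons) > 0L) {
      rejected <- rbind(rejected,
                        data.frame(case_id = cid,
                                   reason = paste(unique(reasons), collapse = "; ")))
    } else {
      cases[[cid]] <- do.call(case_record, rec[c(
        "case_id", "weight", "creatinine", "schedule", "observations",
        "gestational_age")])
    }
  }
  mg_cohort(cases, rejected)
}

# normalization on the bare list, before case_record validation
normalize_times_raw <- function(rec) {
  sched <- rec$schedule
  bolus_times <- sched$time[sched$kind == "bolus"]
  t0 <- min(bolus_times)  # anchor: the FIRST bolus
  if (t0 != 0) {
    ev <- as.data.frame(sched)
    ev$time <- ev$time - t0
    keep <- ev$time >= 0
    ev <- ev[keep, , drop = FALSE]
    tend <- max(attr(sched, "treatment_end") - t0, max(ev$time))
    rec$schedule <- dosing_schedule(ev, treatment_end = tend)
    rec$observations$time <- rec$observations$time - t0
  }
  pre <- rec$observations$time < 0
  if (any(pre)) {
    warning(sprintf("case %s: dropped %d observation(s) before first bolus",
                    rec$case_id, sum(pre)))
    rec$observations <- rec$observations[!pre, , drop = FALSE]
  }
  attr(rec$observations, "dropped_pre_bolus") <-
    sum(pre) + (attr(rec$observations, "dropped_pre_bolus") %||% 0L)
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a case to the time-since-first-bolus axis
#'
#' Shifts all dosing-event and observation times so the first bolus is at
#' time 0; observations drawn before the first bolus are dropped (their
#' count is kept in attribute `dropped_pre_bolus` of the observation
#' table, and a warning is issued).  Idempotent.
#'
#' @param case a [case_record()].
#' @return The normalized `case_record`.
#' @export
normalize_times <- function(case) {
  stopifnot(inherits(case, "case_record"))
  rec <- normalize_times_raw(unclass(case))
  do.call(case_record, rec[c("case_id", "weight", "creatinine", "schedule",
                             "observations", "gestational_age")])
}

#' Write a cohort to the three tidy CSV files
#'
#' Inverse of [read_cohort()]: emits `covariates.csv`, `dosing.csv` and
#' `observations.csv` under `dir`.  The end of treatment is encoded as a
#' trailing `stop` event in the dosing file, so a written cohort
#' round-trips through [read_cohort()] content-identically.
#'
#' @param cohort an `mg_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mg_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cov <- cohort_covariates(cohort)
  names(cov) <- c("case_id", "weight_kg", "creatinine_umol_L",
                  "gestational_age_weeks")
  dos <- do.call(rbind, lapply(unname(cohort$cases), function(cs) {
    ev <- as.data.frame(cs$schedule)
    tend <- treatment_end(cs$schedule)
    if (!(ev$kind[nrow(ev)] == "stop" && ev$time[nrow(ev)] == tend)) {
      ev <- rbind(ev, data.frame(time = tend, kind = "stop", dose = NA_real_,
                                 rate = 0, bolus_duration = NA_real_))
    }
    data.frame(case_id = cs$case_id, time = ev$time, kind = ev$kind,
               dose_g = ev$dose, rate_g_per_h = ev$rate,
               bolus_duration_h = ev$bolus_duration)
  }))
  ob <- do.call(rbind, lapply(unname(cohort$cases), function(cs) {
    data.frame(case_id = cs$case_id, time = cs$observations$time,
               conc_mmol_L = cs$observations$conc,
               aberrant = cs$observations$aberrant)
  }))
  paths <- file.path(dir, c("covariates.csv", "dosing.csv", "observations.csv"))
  utils::write.csv(cov, paths[1L], row.names = FALSE)
  utils::write.csv(dos, paths[2L], row.names = FALSE)
  utils::write.csv(ob, paths[3L], row.names = FALSE)
  invisible(paths)
}
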