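#' Per-case time-to-target event records
#'
#' Event time = time of the first non-aberrant measured concentration
#' strictly above `target`; cases never measured above target are
#' censored at `min(last observation time, horizon)`.  Events after the
#' horizon count as censored at the horizon.
#'
#' @param cohort an `mg_cohort`.
#' @param target target concentration (mmol/L), default 2.0; exceedance
#'   is strict (`>`).
#' @param horizon analysis horizon (h), default 25.
#' @param flag logical: screen observations with [flag_aberrant()] first
#'   (default TRUE), so spurious spikes do not count as events.
#' @param ... passed to [flag_aberrant()].
#' @return data.frame `case_id`, `time` (h), `event` (logical), plus the
#'   case covariates `weight` and `creatinine` for stratification.
#' @export
event_times <- function(cohort, target = 2.0, horizon = 25, flag = TRUE, ...) {
  stopifnot(inherits(cohort, "mg_cohort"), target > 0, horizon > 0)
  do.call(rbind, lapply(unname(cohort$cases), function(cs) {
    obs <- if (flag) flag_aberrant(cs$observations, ...) else cs$observations
    obs <- obs[!obs$aberrant, , drop = FALSE]
    hit <- which(obs$conc > target)
    if (length(hit) > 0L && obs$time[hit[1L]] <= horizon) {
      tt <- obs$time[hit[1L]]
      ev <- TRUE
    } else {
      tt <- min(max(obs$time), horizon)
      ev <- FALSE
    }
    data.frame(case_id = cs$case_id, time = tt, event = ev,
               weight = cs$weight, creatinine = cs$creatinine)
  }))
}

#' Kaplan-Meier product-limit estimate with Greenwood confidence bands
#'
#' The product-limit estimator computed from formulas: at each distinct
#' event time \eqn{t_j} with \eqn{d_j} events among \eqn{n_j} at risk,
#' \eqn{S(t) = \prod_{t_j \le t} (1 - d_j / n_j)}.  Ties between an event
#' and a censoring at the same time are resolved by the usual convention
#' that censored cases are still at risk at that time.  The 95% band uses
#' the Greenwood variance on the log scale,
#' \eqn{\widehat{Var}[\log S(t)] = \sum_{t_j \le t} d_j / (n_j (n_j - d_j))},
#' with `exp(log S +/- z * se)` clipped to `[0, 1]`.
#'
#' @param records event data.frame (`time`, `event`) from
#'   [event_times()].
#' @param conf confidence level, default 0.95.
#' @return An object of class `km_fit`: data.frame with one row per
#'   distinct observed time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `lower`, `upper`); `S(0) = 1` implicitly before the first
#'   row.
#' @seealso [km_survival_at()], [success_at()], [logrank_test()]
#' @export
km_estimate <- function(records, conf = 0.95) {
  stopifnot(all(c("time", "event") %in% names(records)),
            nrow(records) >= 1L, all(records$time > 0))
  tt <- sort(unique(records$time))
  n <- nrow(records)
  surv <- 1
  varlog <- 0
  out <- data.frame(time = tt, n_risk = NA_real_, n_event = NA_real_,
                    n_censor = NA_real_, surv = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  for (j in seq_along(tt)) {
    at_risk <- sum(records$time >= tt[j])
    d <- sum(records$time == tt[j] & records$event)
    cns <- sum(records$time == tt[j] & !records$event)
    if (d > 0) {
      surv <- surv * (1 - d / at_risk)
      if (at_risk > d) {
        varlog <- varlog + d / (at_risk * (at_risk - d))
      } else {
        varlog <- Inf
      }
    }
    se <- sqrt(varlog)
    if (surv > 0 && is.finite(se)) {
      lo <- min(max(exp(log(surv) - z * se), 0), 1)
      up <- min(max(exp(log(surv) + z * se), 0), 1)
    } else {
      lo <- if (surv == 0) 0 else NA_real_
      up <- if (surv == 0) 0 else NA_real_
    }
    out[j, -1L] <- c(at_risk, d, cns, surv, lo, up)
  }
  structure(out, class = c("km_fit", "data.frame"))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %d distinct times, final S = %.3f\n",
              nrow(x), x$surv[nrow(x)]))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Survival probability at a time point
#'
#' Right-continuous step-function lookup of the product-limit estimate;
#' `S(t) = 1` before the first observed time.  Beyond the last observed
#' time the last value is carried forward.
#'
#' @param km a [km_estimate()] fit.
#' @param t time (h); vectorized.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_fit"))
  idx <- findInterval(t, km$time)
  ifelse(idx == 0L, 1, km$surv[pmax(idx, 1L)])
}

#' Proportion of cases having reached target by time t
#'
#' `1 - S(t)` from the product-limit estimate: the cumulative proportion
#' of women whose measured concentration has exceeded the target.
#'
#' @param km a [km_estimate()] fit.
#' @param t time (h); vectorized.
#' @return Success proportions in `[0, 1]`.
#' @export
success_at <- function(km, t) {
  1 - km_survival_at(km, t)
}

#' Stratify cases into covariate quartile groups
#'
#' Rank-based quartiles: cases ordered by the covariate (ties broken by
#' `case_id` order, deterministically) and split into four groups whose
#' sizes differ by at most one, labelled Q1 (lowest) to Q4 (highest).
#'
#' @param records data.frame with `case_id` and the covariate column
#'   (e.g. from [event_times()]).
#' @param covariate "weight" or "creatinine".
#' @return The input with a `stratum` factor column (Q1-Q4) added.
#' @export
stratify_quartiles <- function(records, covariate = c("weight", "creatinine")) {
  covariate <- match.arg(covariate)
  stopifnot(covariate %in% names(records), nrow(records) >= 4L)
  x <- records[[covariate]]
  if (length(unique(x)) == 1L) {
    stop("covariate is constant across cases: quartile strata are undefined")
  }
  ord <- order(x, records$case_id)
  grp <- integer(nrow(records))
  # sizes differing by at most one: distribute the remainder to the
  # lowest-rank groups
  sizes <- rep(nrow(records) %/% 4L, 4L)
  rem <- nrow(records) %% 4L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  grp[ord] <- rep(1:4, times = sizes)
  records$stratum <- factor(paste0("Q", grp), levels = paste0("Q", 1:4))
  records
}

#' Log-rank test across groups
#'
#' The standard (unweighted) log-rank test computed from formulas.  At
#' each distinct event time \eqn{t_j} with \eqn{d_j} total events among
#' \eqn{n_j} at risk, group \eqn{g}'s expected events are
#' \eqn{e_{gj} = d_j n_{gj} / n_j} and the covariance of the observed
#' counts is the multivariate hypergeometric
#' \eqn{V_{ghj} = d_j (n_j - d_j) / (n_j - 1) \,
#'   [\delta_{gh} n_{gj} / n_j - n_{gj} n_{hj} / n_j^2]}.
#' The statistic \eqn{(O - E)^T V^{-} (O - E)} over the first \eqn{k - 1}
#' groups is referenced to a chi-square distribution with \eqn{k - 1}
#' degrees of freedom.
#'
#' @param records event data.frame with `time`, `event` and a `stratum`
#'   (or `group`) column.
#' @param group optional name of the grouping column; defaults to
#'   `stratum` if present, else `group`.
#' @return list with `chisq`, `df`, `p`, and the per-group table
#'   `observed` / `expected`.
#' @export
logrank_test <- function(records, group = NULL) {
  if (is.null(group)) {
    group <- if ("stratum" %in% names(records)) "stratum" else "group"
  }
  stopifnot(all(c("time", "event", group) %in% names(records)))
  g <- factor(records[[group]])
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2L) stop("log-rank test needs at least 2 groups")
  ev_times <- sort(unique(records$time[records$event]))
  O <- stats::setNames(numeric(k), levels(g))
  E <- stats::setNames(numeric(k), levels(g))
  V <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  for (tj in ev_times) {
    at_risk <- records$time >= tj
    nj <- sum(at_risk)
    dj <- sum(records$time == tj & records$event)
    if (nj <= 1L) next
    ng <- tapply(at_risk, g, sum)
    ng[is.na(ng)] <- 0
    dg <- tapply(records$time == tj & records$event, g, sum)
    dg[is.na(dg)] <- 0
    O <- O + dg
    E <- E + dj * ng / nj
    fac <- dj * (nj - dj) / (nj - 1)
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        V[a, b] <- V[a, b] +
          fac * ((a == b) * ng[a] / nj - ng[a] * ng[b] / nj^2)
      }
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chisq <- if (all(abs(u) < 1e-12)) 0 else {
    sol <- tryCatch(solve(Vk, u), error = function(e) NULL)
    if (is.null(sol)) {
      # singular covariance (e.g. a group with no one ever at risk):
      # generalized inverse via eigen decomposition
      eg <- eigen(Vk, symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-10
      sol <- eg$vectors[, pos, drop = FALSE] %*%
        ((t(eg$vectors[, pos, drop = FALSE]) %*% u) / eg$values[pos])
      drop(crossprod(u, sol))
    } else {
      drop(crossprod(u, sol))
    }
  }
  df <- k - 1L
  list(chisq = as.numeric(chisq), df = df,
       p = stats::pchisq(as.numeric(chisq), df, lower.tail = FALSE),
       observed = O, expected = E)
}
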