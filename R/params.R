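#' Pharmacokinetic parameter set for one subject
#'
#' Bundles the structural two-compartment parameters, the endogenous
#' magnesium baseline and the labelled-dose conversion factor.  All rate
#' and volume parameters refer to elemental magnesium amounts in mmol;
#' dosing inputs are labelled grams of magnesium sulfate and are converted
#' through `dose_to_amount`.
#'
#' @param CL clearance (L/h), > 0.
#' @param V1 central volume of distribution (L), > 0.
#' @param Q intercompartmental clearance (L/h), >= 0.  `Q = 0` collapses
#'   the model to one compartment; [hybrid_constants()] refuses it but the
#'   concentration engine handles the limit in closed form.
#' @param V2 peripheral volume of distribution (L), > 0.
#' @param baseline endogenous (pre-treatment) serum magnesium (mmol/L),
#'   treated as a flat additive constant.  Default 0.74 mmol/L.
#' @param dose_to_amount mmol elemental Mg per labelled gram of MgSO4
#'   dose.  Default 4.06 mmol/g (heptahydrate, MgSO4·7H2O, 246.47 g/mol).
#'
#' @return An object of class `pk_params`: a list with the six fields plus
#'   the derived micro constants `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`.
#' @seealso [hybrid_constants()], [individualize()], [predict_profile()]
#' @export
#' @examples
#' p <- pk_params(CL = 4, V1 = 20, Q = 2, V2 = 30)
#' p$k10
pk_params <- function(CL, V1, Q, V2, baseline = 0.74, dose_to_amount = 4.06) {
  stopifnot(
    is.numeric(CL), length(CL) == 1L, CL > 0,
    is.numeric(V1), length(V1) == 1L, V1 > 0,
    is.numeric(Q), length(Q) == 1L, Q >= 0,
    is.numeric(V2), length(V2) == 1L, V2 > 0,
    is.numeric(baseline), length(baseline) == 1L, baseline >= 0,
    is.numeric(dose_to_amount), length(dose_to_amount) == 1L,
    dose_to_amount > 0
  )
  structure(
    list(
      CL = CL, V1 = V1, Q = Q, V2 = V2,
      baseline = baseline, dose_to_amount = dose_to_amount,
      k10 = CL / V1, k12 = Q / V1, k21 = Q / V2
    ),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params>\n")
  cat(sprintf("  CL = %g L/h, V1 = %g L, Q = %g L/h, V2 = %g L\n",
              x$CL, x$V1, x$Q, x$V2))
  cat(sprintf("  baseline = %g mmol/L, dose_to_amount = %g mmol/g\n",
              x$baseline, x$dose_to_amount))
  if (x$Q > 0) {
    hc <- hybrid_constants(x)
    cat(sprintf("  alpha = %.5g /h, beta = %.5g /h\n", hc[["alpha"]], hc[["beta"]]))
  } else {
    cat("  Q = 0: one-compartment limit\n")
  }
  invisible(x)
}

#' Hybrid (macro) rate constants of the two-compartment model
#'
#' Computes the fast and slow disposition rate constants `alpha` and
#' `beta`: the roots of \eqn{s^2 + (k10 + k12 + k21) s + k10 k21 = 0},
#' where `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`.  By Vieta,
#' `alpha * beta = k10 * k21` and `alpha + beta = k10 + k12 + k21`.
#'
#' @param params a [pk_params()] object with `Q > 0`.
#' @return Named numeric vector `c(alpha = , beta = )`, with
#'   `alpha > beta > 0` (units 1/h).
#' @export
#' @examples
#' hybrid_constants(pk_params(CL = 1, V1 = 1, Q = 1, V2 = 1))
hybrid_constants <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  if (params$Q <= 0) {
    stop("Q = 0 gives a degenerate (one-compartment) model; ",
         "hybrid constants are undefined. Use the one-compartment limit.")
  }
  s <- params$k10 + params$k12 + params$k21
  p <- params$k10 * params$k21
  disc <- sqrt(s^2 - 4 * p)
  alpha <- (s + disc) / 2
  # computing beta as p / alpha avoids cancellation when disc ~ s
  beta <- p / alpha
  c(alpha = alpha, beta = beta)
}

#' Covariate model for individualizing typical PK parameters
#'
#' Multiplicative covariate functions on the structural parameters,
#' anchored at reference covariate values: each adjusted parameter is
#' `typical * f(weight) * g(creatinine)` with `f`, `g` either a power law
#' `(x / ref)^exponent` or a linear form `1 + slope * (x - ref)`.
#' Evaluating at the reference covariates returns the typical values
#' exactly.
#'
#' @param ref_weight reference body weight (kg).
#' @param ref_creatinine reference serum creatinine (umol/L).
#' @param terms a list of covariate terms; each term is a list with
#'   fields `param` (one of "CL","V1","Q","V2"), `covariate` (one of
#'   "weight","creatinine"), `form` ("power" or "linear") and `coef`
#'   (the exponent for power, the slope per unit for linear).
#' @return An object of class `covariate_model`.
#' @seealso [individualize()], [default_covariate_model()]
#' @export
covariate_model <- function(ref_weight, ref_creatinine, terms) {
  stopifnot(ref_weight > 0, ref_creatinine > 0, is.list(terms))
  for (tm in terms) {
    stopifnot(
      is.list(tm),
      tm$param %in% c("CL", "V1", "Q", "V2"),
      tm$covariate %in% c("weight", "creatinine"),
      tm$form %in% c("power", "linear"),
      is.numeric(tm$coef), length(tm$coef) == 1L, is.finite(tm$coef)
    )
  }
  structure(
    list(ref_weight = ref_weight, ref_creatinine = ref_creatinine,
         terms = terms),
    class = "covariate_model"
  )
}

#' Placeholder typical parameter values
#'
#' The published population model this package is built to exercise is not
#' reproduced here; these typical values are a documented placeholder
#' (CL = 4 L/h, V1 = 20 L, Q = 2 L/h, V2 = 30 L) with plausible magnesium
#' disposition: a slow half-life of about 17 h so that a constant infusion
#' approaches steady state at roughly 24-48 h.  Transcribe the published
#' estimates into the parameter config before any clinical-mimicking run.
#'
#' @inheritParams pk_params
#' @return A [pk_params()] object.
#' @export
default_pk_params <- function(baseline = 0.74, dose_to_amount = 4.06) {
  pk_params(CL = 4, V1 = 20, Q = 2, V2 = 30,
            baseline = baseline, dose_to_amount = dose_to_amount)
}

#' Placeholder covariate model
#'
#' Allometric body weight on clearance (exponent 0.75) and on the volumes
#' (exponent 1), and inverse serum creatinine on clearance (power
#' exponent -1, reflecting renal elimination of magnesium), anchored at
#' 70 kg and 60 umol/L.  Placeholder — transcribe the published covariate
#' functions before clinical-mimicking runs.
#'
#' @return A [covariate_model()] object.
#' @export
default_covariate_model <- function() {
  covariate_model(
    ref_weight = 70, ref_creatinine = 60,
    terms = list(
      list(param = "CL", covariate = "weight",     form = "power", coef = 0.75),
      list(param = "V1", covariate = "weight",     form = "power", coef = 1),
      list(param = "V2", covariate = "weight",     form = "power", coef = 1),
      list(param = "CL", covariate = "creatinine", form = "power", coef = -1)
    )
  )
}

#' Individualize typical PK parameters by body weight and creatinine
#'
#' Applies the multiplicative covariate functions of a [covariate_model()]
#' to the typical parameter values.  At the reference covariates the
#' typical values are returned unchanged.
#'
#' @param typical a [pk_params()] object holding the typical values.
#' @param covmodel a [covariate_model()].
#' @param weight body weight (kg), > 0.
#' @param creatinine serum creatinine (umol/L), > 0.
#' @return A [pk_params()] object with adjusted CL/V1/Q/V2.
#' @export
#' @examples
#' individualize(default_pk_params(), default_covariate_model(),
#'               weight = 84, creatinine = 57)
individualize <- function(typical, covmodel, weight, creatinine) {
  stopifnot(inherits(typical, "pk_params"), inherits(covmodel, "covariate_model"))
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0) {
    stop("weight must be a single positive number (kg)")
  }
  if (!is.numeric(creatinine) || length(creatinine) != 1L ||
      !is.finite(creatinine) || creatinine <= 0) {
    stop("creatinine must be a single positive number (umol/L)")
  }
  vals <- c(CL = typical$CL, V1 = typical$V1, Q = typical$Q, V2 = typical$V2)
  cov_val <- c(weight = weight, creatinine = creatinine)
  cov_ref <- c(weight = covmodel$ref_weight, creatinine = covmodel$ref_creatinine)
  for (tm in covmodel$terms) {
    x <- cov_val[[tm$covariate]]
    r <- cov_ref[[tm$covariate]]
    fac <- switch(tm$form,
      power  = (x / r)^tm$coef,
      linear = 1 + tm$coef * (x - r)
    )
    if (!is.finite(fac) || fac <= 0) {
      stop(sprintf("covariate term on %s yields non-positive factor %g",
                   tm$param, fac))
    }
    vals[[tm$param]] <- vals[[tm$param]] * fac
  }
  pk_params(CL = vals[["CL"]], V1 = vals[["V1"]], Q = vals[["Q"]],
            V2 = vals[["V2"]], baseline = typical$baseline,
            dose_to_amount = typical$dose_to_amount)
}

#' Steady-state concentration under a constant maintenance rate
#'
#' Closed form `baseline + rate * dose_to_amount / CL`: at steady state
#' the infusion input balances clearance, independently of the volumes.
#'
#' @param rate maintenance infusion rate (g/h of labelled MgSO4), >= 0.
#' @param params a [pk_params()] object.
#' @return Total serum magnesium at steady state (mmol/L).
#' @export
#' @examples
#' steady_state(1, pk_params(CL = 4, V1 = 20, Q = 2, V2 = 30))  # 1.755
steady_state <- function(rate, params) {
  stopifnot(inherits(params, "pk_params"), is.numeric(rate), all(rate >= 0))
  params$baseline + rate * params$dose_to_amount / params$CL
}
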