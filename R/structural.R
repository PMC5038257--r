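## Structural models: closed-form one-compartment first-order absorption with
## lag time, and transit-compartment absorption evaluated as the exact
## convolution of the gamma-density transit input with the analytic
## disposition impulse response.

#' One-compartment, first-order absorption with lag time
#'
#' Closed-form plasma concentration after a single oral dose:
#' zero for `t <= tlag`, otherwise the standard Bateman solution evaluated at
#' `t - tlag`. The absorption/elimination rate degeneracy `ka = ke` is handled
#' by the equal-rates limiting form when `|ka - ke|/ke < 1e-6`.
#'
#' @param t time since dose, h (vectorised).
#' @param dose dose amount, mg.
#' @param F bioavailability fraction.
#' @param CL_F apparent clearance, L/h.
#' @param V_F apparent volume, L.
#' @param ka absorption rate constant, 1/h.
#' @param tlag absorption lag time, h.
#' @return concentration, mg/L.
#' @export
conc_one_cpt_lag <- function(t, dose, F, CL_F, V_F, ka, tlag) {
  if (any(t < 0)) stop("t must be non-negative")
  if (any(c(dose, F, CL_F, V_F, ka) <= 0) || tlag < 0) {
    stop("dose, F, CL_F, V_F, ka must be positive and tlag >= 0")
  }
  ke <- CL_F / V_F
  tau <- t - tlag
  out <- numeric(length(t))
  pos <- tau > 0
  if (any(pos)) {
    tp <- tau[pos]
    if (abs(ka - ke) / ke < 1e-6) {
      out[pos] <- F * dose * ka * tp * exp(-ka * tp) / V_F
    } else {
      out[pos] <- F * dose * ka / (V_F * (ka - ke)) * (exp(-ke * tp) - exp(-ka * tp))
    }
  }
  out
}

#' Transit-compartment drug input rate
#'
#' Continuous (gamma-function) transit formulation that allows a non-integer
#' number of transit compartments NN:
#' \deqn{rate(t) = F \cdot dose \cdot k_{tr} (k_{tr} t)^{NN} e^{-k_{tr} t} / \Gamma(NN+1)}
#' with \eqn{k_{tr} = (NN+1)/MTT}. Integrates to `F * dose`; `NN = 0` reduces
#' to first-order input with rate constant `1/MTT`.
#'
#' @param t time since dose, h (vectorised).
#' @param dose dose amount, mg.
#' @param F bioavailability fraction.
#' @param MTT mean transit time, h (> 0).
#' @param NN number of transit compartments (>= 0, non-integer allowed).
#' @return input rate, mg/h.
#' @export
transit_input_rate <- function(t, dose, F, MTT, NN) {
  if (any(t < 0)) stop("t must be non-negative")
  if (MTT <= 0) stop("MTT must be positive")
  if (NN < 0) stop("NN must be >= 0")
  ktr <- (NN + 1) / MTT
  ## log-scale evaluation; (ktr t)^NN at t = 0 is 1 for NN = 0, 0 otherwise
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- F * dose * exp(log(ktr) + NN * (log(ktr) + log(t[pos])) -
                               ktr * t[pos] - lgamma(NN + 1))
  if (NN == 0) out[!pos] <- F * dose * ktr * exp(-ktr * t[!pos])
  out
}

## Disposition impulse response: central-compartment concentration after a
## unit amount placed in the absorption depot (or directly in the central
## compartment for "direct"). Returns a vectorised function of t.
disposition_impulse <- function(disposition, params, depot = TRUE) {
  CL <- params[["CL"]]; V <- params[["V"]]
  if (disposition == "one_compartment") {
    ke <- CL / V
    if (!depot) return(function(t) exp(-ke * t) / V)
    ka <- params[["ka"]]
    if (abs(ka - ke) / ke < 1e-6) {
      function(t) ka * t * exp(-ka * t) / V
    } else {
      function(t) ka / (V * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
    }
  } else {
    k10 <- CL / V; k12 <- params[["Q"]] / V; k21 <- params[["Q"]] / params[["Vp"]]
    s <- k10 + k12 + k21
    disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    if (!depot) {
      A <- (alpha - k21) / (alpha - beta) / V
      B <- (k21 - beta) / (alpha - beta) / V
      return(function(t) A * exp(-alpha * t) + B * exp(-beta * t))
    }
    ka <- params[["ka"]]
    ## nudge away from exact pole ka == alpha or ka == beta
    if (min(abs(ka - alpha), abs(ka - beta)) < 1e-8 * ka) ka <- ka * (1 + 1e-7)
    A <- (k21 - alpha) / ((ka - alpha) * (beta - alpha)) / V
    B <- (k21 - beta) / ((ka - beta) * (alpha - beta)) / V
    C <- (k21 - ka) / ((alpha - ka) * (beta - ka)) / V
    function(t) ka * (A * exp(-alpha * t) + B * exp(-beta * t) + C * exp(-ka * t))
  }
}

## Convolution of the transit input with an impulse response, by adaptive
## quadrature per time point (relative tolerance 1e-8).
conc_transit_conv <- function(t, dose, params, disposition, depot,
                              rel_tol = 1e-8) {
  F <- params[["F"]]; MTT <- params[["MTT"]]; NN <- params[["NN"]]
  h <- disposition_impulse(disposition, params, depot = depot)
  one <- function(ti) {
    if (ti <= 0) return(0)
    res <- tryCatch(
      integrate(function(u) transit_input_rate(u, dose, F, MTT, NN) * h(ti - u),
                lower = 0, upper = ti, rel.tol = rel_tol, abs.tol = 0,
                subdivisions = 400L, stop.on.error = TRUE),
      error = function(e) {
        stop(sprintf(
          "transit-model integration failed at t=%g (dose=%g, MTT=%g, NN=%g, CL=%g, V=%g): %s",
          ti, dose, MTT, NN, params[["CL"]], params[["V"]], conditionMessage(e)))
      })
    res$value
  }
  vapply(t, one, numeric(1))
}

#' Transit-absorption concentration, two-compartment disposition
#'
#' Drug passes through a continuous chain of transit compartments
#' ([transit_input_rate()]), then a first-order depot (`ka`), then a central
#' compartment exchanging with a peripheral compartment, with first-order
#' elimination (`CL`) from the central compartment. Evaluated as the exact
#' convolution integral with relative tolerance 1e-8; integrator failures
#' raise a diagnostic naming the parameter values.
#'
#' @param t time since dose, h (vectorised).
#' @param dose dose, mg.
#' @param params named vector/list with `F`, `MTT`, `NN`, `ka`, `CL`, `V`,
#'   `Q`, `Vp`.
#' @return concentration, mg/L.
#' @export
conc_two_cpt_transit <- function(t, dose, params) {
  params <- unlist(params)
  .check_transit_params(t, dose, params, c("F", "MTT", "NN", "ka", "CL", "V", "Q", "Vp"))
  conc_transit_conv(t, dose, params, "two_compartment", depot = TRUE)
}

#' Transit-absorption concentration, one-compartment disposition
#'
#' As [conc_two_cpt_transit()] but with a single disposition compartment.
#' With `ka` fixed at 50/h the depot is quasi-instantaneous and the profile
#' approaches the transit-direct input model.
#'
#' @param t time since dose, h (vectorised).
#' @param dose dose, mg.
#' @param params named vector/list with `F`, `MTT`, `NN`, `ka`, `CL`, `V`.
#' @return concentration, mg/L.
#' @export
conc_one_cpt_transit <- function(t, dose, params) {
  params <- unlist(params)
  .check_transit_params(t, dose, params, c("F", "MTT", "NN", "ka", "CL", "V"))
  conc_transit_conv(t, dose, params, "one_compartment", depot = TRUE)
}

#' @rdname conc_one_cpt_transit
#' @export
conc_transit_direct <- function(t, dose, params) {
  params <- unlist(params)
  .check_transit_params(t, dose, params, c("F", "MTT", "NN", "CL", "V"))
  conc_transit_conv(t, dose, params, "one_compartment", depot = FALSE)
}

.check_transit_params <- function(t, dose, params, need) {
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  if (any(t < 0)) stop("t must be non-negative")
  pos <- setdiff(need, "NN")
  if (dose <= 0 || any(params[pos] <= 0)) stop("dose and parameters must be positive")
  if (params[["NN"]] < 0) stop("NN must be >= 0")
  invisible(TRUE)
}

#' Steady-state concentration by superposition
#'
#' Once-daily steady state: the profile within a dosing interval is the sum of
#' single-dose profiles from the current and all prior doses,
#' `C_ss(t) = sum_k f(t + k * interval)`, truncated once the next term's
#' relative contribution falls below `tol` (default 1e-8). The returned
#' profile is periodic with the dosing interval.
#'
#' @param t_in_interval time within the dosing interval, h (vectorised; values
#'   are reduced modulo the interval).
#' @param regimen a [dose_regimen()].
#' @param single_dose_fn function of time returning the single-dose
#'   concentration for this regimen's dose.
#' @param tol relative truncation tolerance.
#' @return concentration, mg/L.
#' @export
steady_state_conc <- function(t_in_interval, regimen, single_dose_fn, tol = 1e-8) {
  ii <- regimen$interval
  t <- t_in_interval %% ii
  total <- single_dose_fn(t)
  for (k in seq_len(regimen$n_prior_doses)) {
    term <- single_dose_fn(t + k * ii)
    total <- total + term
    if (k >= 2 && max(term) <= tol * max(max(total), .Machine$double.xmin)) {
      return(total)
    }
  }
  stop("steady-state superposition did not converge within ",
       regimen$n_prior_doses, " prior doses")
}

#' Evaluate a model's concentration profile
#'
#' Dispatches to the structural solution declared by the model spec, for a
#' single dose or at once-daily steady state (by superposition).
#'
#' @param model a [pk_model_spec()].
#' @param params named individual parameter values (see [pk_model_spec()]).
#' @param dose dose, mg; or a [dose_regimen()] when `steady_state = TRUE`.
#' @param times evaluation times, h.
#' @param steady_state evaluate the periodic steady-state profile?
#' @param ii dosing interval for steady state, h.
#' @return concentration, mg/L.
#' @export
model_conc <- function(model, params, dose, times, steady_state = FALSE, ii = 24) {
  params <- unlist(params)
  regimen <- if (inherits(dose, "tbpk_regimen")) dose else dose_regimen(dose, ii)
  single <- function(t) {
    if (model$absorption == "first_order_lag") {
      conc_one_cpt_lag(t, regimen$amount, params[["F"]], params[["CL"]],
                       params[["V"]], params[["ka"]], params[["tlag"]])
    } else if (model$absorption == "transit_direct") {
      conc_transit_direct(t, regimen$amount, params)
    } else if (model$disposition == "two_compartment") {
      conc_two_cpt_transit(t, regimen$amount, params)
    } else {
      conc_one_cpt_transit(t, regimen$amount, params)
    }
  }
  if (steady_state) steady_state_conc(times, regimen, single) else single(times)
}
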