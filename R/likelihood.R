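## Population likelihood: map population parameters + random effects to
## individual parameters, combined residual error, and the per-subject
## conditional data likelihood with left-censored (M3) BLQ handling.

#' Individual parameters from typical values and random effects
#'
#' `p_i = p_typical * exp(eta_p) * exp(kappa_p)`, with lognormal
#' interindividual effects `eta` and interoccasion effects `kappa` (the
#' latter specific to the pharmacokinetic occasion being evaluated). Missing
#' names get no perturbation.
#'
#' @param typical named numeric vector of individual typical values.
#' @param eta named numeric vector of interindividual effects (log scale).
#' @param kappa named numeric vector of interoccasion effects for this
#'   occasion (log scale).
#' @return named numeric vector of individual parameter values.
#' @export
individual_params <- function(typical, eta = numeric(), kappa = numeric()) {
  p <- unlist(typical)
  for (re in list(eta, kappa)) {
    if (!length(re)) next
    if (is.null(names(re)) || !all(names(re) %in% names(p))) {
      stop("random effects must be named after typical parameters")
    }
    p[names(re)] <- p[names(re)] * exp(re)
  }
  p
}

#' Combined residual-error standard deviation
#'
#' `sqrt(a^2 + (b * pred)^2)`: additive component `a` (mg/L) plus
#' proportional component `b` (fraction of the prediction).
#'
#' @param pred predicted concentration, mg/L (>= 0).
#' @param a additive SD, mg/L.
#' @param b proportional fraction.
#' @return residual SD, mg/L.
#' @export
residual_sd <- function(pred, a, b) {
  if (any(pred < 0)) stop("pred must be >= 0")
  sqrt(a^2 + (b * pred)^2)
}

#' Log-likelihood of one observation, with M3 censoring
#'
#' Non-BLQ observations contribute the Gaussian log-density of the observed
#' concentration given the prediction and residual SD. BLQ observations are
#' left-censored at the LLOQ and contribute
#' `log Phi((lloq - pred) / sd)` (the M3 method). All arguments are
#' vectorised.
#'
#' @param obs observed concentration, mg/L (`NA` allowed where `blq`).
#' @param pred model prediction, mg/L.
#' @param sd residual SD, mg/L (> 0).
#' @param lloq lower limit of quantification, mg/L (needed where `blq`).
#' @param blq logical censoring flag.
#' @return log-density per observation.
#' @export
obs_loglik <- function(obs, pred, sd, lloq = NA_real_, blq = FALSE) {
  n <- max(length(obs), length(pred), length(sd), length(lloq), length(blq))
  obs <- rep_len(obs, n); pred <- rep_len(pred, n); sd <- rep_len(sd, n)
  lloq <- rep_len(lloq, n); blq <- rep_len(blq, n)
  if (any(sd <= 0)) stop("sd must be positive")
  if (any(blq & !is.finite(lloq))) stop("BLQ observations need an LLOQ")
  out <- numeric(n)
  if (any(blq)) {
    out[blq] <- pnorm((lloq[blq] - pred[blq]) / sd[blq], log.p = TRUE)
  }
  if (any(!blq)) {
    if (any(is.na(obs[!blq]))) stop("non-BLQ observations need a concentration")
    out[!blq] <- dnorm(obs[!blq], pred[!blq], sd[!blq], log = TRUE)
  }
  out
}

## Predicted concentrations for one subject's observation records.
## Predose records are evaluated on the steady-state profile at the end of the
## prior dosing interval; post-dose records on the observed-dose profile.
subject_predictions <- function(obs, model, params, regimen) {
  stopifnot(all(c("time", "occasion") %in% names(obs)))
  if (!is.list(params) || !is.null(names(params)) && is.numeric(params[[1]]) &&
      !all(c("predose", "intensive") %in% names(params))) {
    params <- list(predose = unlist(params), intensive = unlist(params))
  }
  pred <- numeric(nrow(obs))
  is_pre <- obs$occasion == "predose"
  if (any(is_pre)) {
    pred[is_pre] <- model_conc(model, params$predose, regimen,
                               times = rep(regimen$interval, sum(is_pre)),
                               steady_state = TRUE)
  }
  if (any(!is_pre)) {
    pred[!is_pre] <- model_conc(model, params$intensive, regimen$amount,
                                times = obs$time[!is_pre])
  }
  pred
}

#' Conditional log-likelihood of one subject's data
#'
#' Sum of [obs_loglik()] over a subject's observation records given fixed
#' individual parameters. Predose records are evaluated on the steady-state
#' profile (superposition over prior once-daily doses); post-dose records on
#' the observed-dose profile. The residual-error model is shared across
#' occasions.
#'
#' @param obs data frame with columns `time`, `dv`, `blq`, `lloq`,
#'   `occasion` (`"predose"` or `"intensive"`).
#' @param model a [pk_model_spec()].
#' @param params named parameter vector, or a list with elements `predose`
#'   and `intensive` when interoccasion effects differ.
#' @param regimen a [dose_regimen()] (the observed dose; also used for the
#'   prior steady-state interval).
#' @param error list with `a` and `b`; defaults to the model's error model.
#' @return scalar log-likelihood.
#' @export
subject_conditional_loglik <- function(obs, model, params, regimen,
                                       error = model$error) {
  if (nrow(obs) == 0) return(0)
  pred <- subject_predictions(obs, model, params, regimen)
  sd <- residual_sd(pred, error$a, error$b)
  sum(obs_loglik(obs$dv, pred, sd, obs$lloq, obs$blq))
}

#' Conditional log-likelihood under a clearance mixture
#'
#' Marginalises the mixture component:
#' `log sum_k pi_k exp(loglik | CL * multiplier_k)`, computed by log-sum-exp.
#'
#' @inheritParams subject_conditional_loglik
#' @param mixture a [mixture_spec()].
#' @return scalar log-likelihood.
#' @export
mixture_conditional_loglik <- function(obs, model, params, regimen, mixture,
                                       error = model$error) {
  stopifnot(inherits(mixture, "tbpk_mixture"))
  comp <- vapply(seq_along(mixture$multipliers), function(k) {
    pk <- if (is.list(params) && all(c("predose", "intensive") %in% names(params))) {
      lapply(params, function(p) {
        p[mixture$param] <- p[mixture$param] * mixture$multipliers[k]; p
      })
    } else {
      p <- unlist(params); p[mixture$param] <- p[mixture$param] * mixture$multipliers[k]; p
    }
    subject_conditional_loglik(obs, model, pk, regimen, error)
  }, numeric(1))
  logsumexp(log(mixture$proportions) + comp)
}
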