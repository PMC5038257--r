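## Model registry: structural/statistical model specifications per drug, with
## defaults set to the final published population estimates.

#' Convert an approximate %CV to a lognormal variance and back
#'
#' Lognormal variabilities are reported as approximate %CV using
#' \eqn{CV = \sqrt{\exp(\omega^2) - 1}}; these two helpers convert between the
#' reporting scale and the variance \eqn{\omega^2} used internally. The
#' simpler first-order convention \eqn{CV \approx \omega} is available via
#' `convention = "sd"`.
#'
#' @param cv variability in percent.
#' @param omega2 lognormal variance.
#' @param convention `"exact"` (default) or `"sd"`.
#' @return `cv_to_omega2`: variance; `omega2_to_cv`: percent CV.
#' @export
cv_to_omega2 <- function(cv, convention = c("exact", "sd")) {
  convention <- match.arg(convention)
  if (isTRUE(any(cv < 0))) stop("cv must be non-negative")
  if (convention == "exact") log(1 + (cv / 100)^2) else (cv / 100)^2
}

#' @rdname cv_to_omega2
#' @export
omega2_to_cv <- function(omega2, convention = c("exact", "sd")) {
  convention <- match.arg(convention)
  if (isTRUE(any(omega2 < 0))) stop("omega2 must be non-negative")
  if (convention == "exact") 100 * sqrt(exp(omega2) - 1) else 100 * sqrt(omega2)
}

#' Once-daily dosing regimen
#'
#' @param amount dose per administration, mg (> 0).
#' @param interval dosing interval, h (default 24, once daily).
#' @param n_prior_doses assumed number of prior doses available when building
#'   a steady-state profile by superposition; the superposition sum truncates
#'   earlier once converged.
#' @return a list of class `tbpk_regimen`.
#' @export
dose_regimen <- function(amount, interval = 24, n_prior_doses = 200L) {
  if (amount <= 0) stop("amount must be positive")
  if (interval <= 0) stop("interval must be positive")
  structure(list(amount = amount, interval = interval,
                 n_prior_doses = as.integer(n_prior_doses)),
            class = "tbpk_regimen")
}

#' Pharmacokinetic model specification
#'
#' Bundles one drug's structural model, typical parameter values, random-effect
#' structure (interindividual and interoccasion variability, both lognormal),
#' combined residual-error model, covariate effects, and optionally a mixture
#' on clearance. Variabilities are supplied as variances (`omega2`); use
#' [cv_to_omega2()] to enter them on the reported %CV scale.
#'
#' @param drug drug name.
#' @param disposition `"one_compartment"` or `"two_compartment"`.
#' @param absorption `"first_order_lag"`, `"transit_then_first_order"`, or
#'   `"transit_direct"`.
#' @param typical named list of typical values. Recognised names: `F` (fixed
#'   to 1), `ka` (1/h), `tlag` (h), `MTT` (h), `NN` (transit compartments,
#'   non-integer allowed), `CL` (L/h), `V` (L), `Q` (L/h), `Vp` (L).
#' @param iiv named numeric vector of interindividual variances (lognormal).
#' @param iov named numeric vector of interoccasion variances (lognormal).
#' @param error list with `a` (additive SD, mg/L) and `b` (proportional
#'   fraction); residual SD is `sqrt(a^2 + (b*pred)^2)`.
#' @param fixed character vector of parameter names whose typical values are
#'   not estimated (always includes `F`).
#' @param covariates list of [covariate_effect()] objects.
#' @param mixture optional [mixture_spec()] on CL.
#' @param n_occasions number of pharmacokinetic occasions (default 2: the
#'   predose steady-state sample and the intensively sampled observed dose).
#' @return an object of class `tbpk_model`.
#' @export
pk_model_spec <- function(drug, disposition = c("one_compartment", "two_compartment"),
                          absorption = c("first_order_lag", "transit_then_first_order",
                                         "transit_direct"),
                          typical, iiv = numeric(), iov = numeric(),
                          error = list(a = 0, b = 0.1),
                          fixed = "F", covariates = list(), mixture = NULL,
                          n_occasions = 2L) {
  disposition <- match.arg(disposition)
  absorption <- match.arg(absorption)
  typical <- as.list(typical)
  if (is.null(typical$F)) typical$F <- 1
  need <- switch(absorption,
                 first_order_lag = c("ka", "tlag"),
                 transit_then_first_order = c("MTT", "NN", "ka"),
                 transit_direct = c("MTT", "NN"))
  need <- c(need, "CL", "V", if (disposition == "two_compartment") c("Q", "Vp"))
  miss <- setdiff(need, names(typical))
  if (length(miss)) stop("missing typical values: ", paste(miss, collapse = ", "))
  pos <- setdiff(need, "NN")
  bad <- vapply(typical[pos], function(v) !is.finite(v) || v <= 0, logical(1))
  if (any(bad)) stop("non-positive typical value(s): ", paste(pos[bad], collapse = ", "))
  if (!is.null(typical$NN) && typical$NN < 0) stop("NN must be >= 0")
  if (any(iiv < 0) || any(iov < 0)) stop("variances must be >= 0")
  if (error$a < 0 || error$b < 0) stop("error components must be >= 0")
  if (!all(c(names(iiv), names(iov)) %in% names(typical))) {
    stop("random effects must target declared parameters")
  }
  fixed <- union("F", fixed)
  structure(list(drug = drug, disposition = disposition, absorption = absorption,
                 typical = typical, iiv = iiv, iov = iov, error = error,
                 fixed = fixed, covariates = covariates, mixture = mixture,
                 n_occasions = as.integer(n_occasions)),
            class = "tbpk_model")
}

#' @export
print.tbpk_model <- function(x, ...) {
  cat(sprintf("<tbpk_model> %s: %s disposition, %s absorption\n",
              x$drug, x$disposition, x$absorption))
  cat("  typical:", paste(sprintf("%s=%g", names(x$typical), unlist(x$typical)),
                          collapse = ", "), "\n")
  if (length(x$iiv)) cat("  IIV on:", paste(names(x$iiv), collapse = ", "), "\n")
  if (length(x$iov)) cat("  IOV on:", paste(names(x$iov), collapse = ", "), "\n")
  cat(sprintf("  error: a=%g mg/L, b=%g\n", x$error$a, x$error$b))
  invisible(x)
}

#' Mixture specification for multimodal clearance
#'
#' A finite mixture on CL (fast/slow acetylator bimodality of isoniazid
#' clearance caused by the NAT2 polymorphism): component k multiplies the
#' typical CL by `multipliers[k]` with prior probability `proportions[k]`.
#'
#' @param param parameter name, `"CL"`.
#' @param multipliers positive component multipliers.
#' @param proportions mixing proportions, summing to 1.
#' @return a list of class `tbpk_mixture`.
#' @export
mixture_spec <- function(param = "CL", multipliers, proportions) {
  if (length(multipliers) != length(proportions)) stop("length mismatch")
  if (any(multipliers <= 0)) stop("multipliers must be > 0")
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    stop("proportions must be non-negative and sum to 1")
  }
  structure(list(param = param, multipliers = multipliers,
                 proportions = proportions), class = "tbpk_mixture")
}

## Published final estimates. Categorical CL multipliers are stored as ratios
## of the printed per-stratum typical values (19.9/25.1 for HIV+, 10.8/19.9
## for LPV/r on top of HIV) so the table values reproduce exactly at the
## reference FFM of 45 kg.
.allo_effects <- function(params_cl, params_v, reference = 45) {
  c(lapply(params_cl, function(p) covariate_effect(p, "allometric", exponent = 0.75,
                                                   reference = reference)),
    lapply(params_v, function(p) covariate_effect(p, "allometric", exponent = 1,
                                                  reference = reference)))
}

#' Default drug models (final published estimates)
#'
#' `rifampin_model()`: one-compartment disposition, first-order absorption
#' with lag time; IOV on F, tlag, ka; IIV on CL; HIV-1 and lopinavir/ritonavir
#' effects reduce CL.
#' `isoniazid_model()`: two-compartment disposition, transit-compartment
#' absorption into a first-order depot; IOV on F, MTT, ka; IIV on CL; HIV-1
#' effect on CL.
#' `pyrazinamide_model()`: one-compartment disposition, transit-compartment
#' absorption with the depot rate constant fixed at 50/h; IOV on F, MTT; IIV
#' on CL; no HIV effect.
#'
#' All clearances and volumes carry allometric scaling on fat-free mass
#' (exponents 0.75 and 1) with the cohort-median reference of 45 kg.
#'
#' @param reference_ffm reference fat-free mass, kg.
#' @return a [pk_model_spec()].
#' @export
rifampin_model <- function(reference_ffm = 45) {
  pk_model_spec(
    drug = "rifampin",
    disposition = "one_compartment",
    absorption = "first_order_lag",
    typical = list(F = 1, tlag = 0.691, ka = 1.21, CL = 25.1, V = 56.4),
    iiv = c(CL = cv_to_omega2(34.3)),
    iov = c(F = cv_to_omega2(29.1), tlag = cv_to_omega2(76.2),
            ka = cv_to_omega2(63.2)),
    error = list(a = 0.196, b = 0.150),
    covariates = c(
      .allo_effects("CL", "V", reference_ffm),
      list(
        covariate_effect("CL", "categorical", when = "hiv_positive",
                         theta = 19.9 / 25.1, label = "HIV+ on CL"),
        covariate_effect("CL", "categorical", when = "art_class == 'pi_lpvr'",
                         theta = 10.8 / 19.9, label = "LPV/r on CL")
      )
    )
  )
}

#' @rdname rifampin_model
#' @export
isoniazid_model <- function(reference_ffm = 45) {
  pk_model_spec(
    drug = "isoniazid",
    disposition = "two_compartment",
    absorption = "transit_then_first_order",
    typical = list(F = 1, MTT = 0.32, NN = 2.04, ka = 1.20,
                   CL = 26.0, V = 31.9, Q = 12.6, Vp = 21.4),
    iiv = c(CL = cv_to_omega2(54.8)),
    iov = c(F = cv_to_omega2(32.3), MTT = cv_to_omega2(92.7),
            ka = cv_to_omega2(17.7)),
    error = list(a = 0.0146, b = 0.131),
    covariates = c(
      .allo_effects(c("CL", "Q"), c("V", "Vp"), reference_ffm),
      list(covariate_effect("CL", "categorical", when = "hiv_positive",
                            theta = 20.02 / 26.0, label = "HIV+ on CL"))
    )
  )
}

#' @rdname rifampin_model
#' @export
pyrazinamide_model <- function(reference_ffm = 45) {
  pk_model_spec(
    drug = "pyrazinamide",
    disposition = "one_compartment",
    absorption = "transit_then_first_order",
    typical = list(F = 1, MTT = 0.74, NN = 2.06, ka = 50, CL = 4.17, V = 41.9),
    iiv = c(CL = cv_to_omega2(29.6)),
    iov = c(F = cv_to_omega2(13.1), MTT = cv_to_omega2(54.5)),
    error = list(a = 1.95, b = 0.107),
    fixed = c("F", "ka"),
    covariates = .allo_effects("CL", "V", reference_ffm)
  )
}

#' Replace a model's random-effect structure or covariates
#'
#' Convenience editors used by the covariate-selection search and by reduced
#' fitting specifications.
#'
#' @param model a [pk_model_spec()].
#' @param iiv,iov named variance vectors (omitted = keep current).
#' @param covariates replacement covariate list.
#' @param add a single [covariate_effect()] to append.
#' @param drop label of an effect to remove.
#' @return the modified model.
#' @export
set_random_effects <- function(model, iiv = NULL, iov = NULL) {
  if (!is.null(iiv)) model$iiv <- iiv
  if (!is.null(iov)) model$iov <- iov
  if (!all(c(names(model$iiv), names(model$iov)) %in% names(model$typical))) {
    stop("random effects must target declared parameters")
  }
  model
}

#' @rdname set_random_effects
#' @export
set_covariates <- function(model, covariates = NULL, add = NULL, drop = NULL) {
  if (!is.null(covariates)) model$covariates <- covariates
  if (!is.null(add)) model$covariates <- c(model$covariates, list(add))
  if (!is.null(drop)) {
    keep <- vapply(model$covariates, function(e) e$label != drop, logical(1))
    model$covariates <- model$covariates[keep]
  }
  model
}
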