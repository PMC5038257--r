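## Covariate engine: fat-free mass, allometric scaling, categorical covariate
## effects applied to individual structural parameters.

## Janmahasatian maximum weight-height-squared constants, by sex
.ffm_constants <- list(
  male   = c(whs_max = 42.92, whs_50 = 30.93),
  female = c(whs_max = 37.99, whs_50 = 35.98)
)

#' Fat-free mass (Janmahasatian model)
#'
#' Empirical sex-specific fat-free mass from total body weight and height:
#' \deqn{FFM = \frac{WHS_{max} \cdot ht^2 \cdot wt}{WHS_{50} \cdot ht^2 + wt}}
#' with \eqn{WHS_{max}} = 42.92 and \eqn{WHS_{50}} = 30.93 for men, and 37.99
#' and 35.98 for women. Over the physiological weight range the result lies
#' strictly between 0 and the body weight.
#'
#' @param sex "male" or "female" (vectorised, recycled against weight/height).
#' @param weight body weight in kg, > 0.
#' @param height height in metres, in (0.5, 2.5).
#' @return fat-free mass in kg.
#' @examples
#' fat_free_mass("male", 51, 1.70)  # ~45 kg
#' @export
fat_free_mass <- function(sex, weight, height) {
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  if (any(weight <= 0)) stop("weight must be positive")
  if (any(height <= 0.5 | height >= 2.5)) stop("height must be in (0.5, 2.5) m")
  n <- max(length(sex), length(weight), length(height))
  sex <- rep_len(sex, n); weight <- rep_len(weight, n); height <- rep_len(height, n)
  whs_max <- ifelse(sex == "male", 42.92, 37.99)
  whs_50 <- ifelse(sex == "male", 30.93, 35.98)
  (whs_max * height^2 * weight) / (whs_50 * height^2 + weight)
}

#' Allometric scaling factor
#'
#' `(size / reference) ^ exponent`, the standard power-law size adjustment
#' applied to clearances (exponent 0.75) and volumes (exponent 1).
#'
#' @param size individual body-size descriptor (kg), > 0.
#' @param reference reference size (kg), > 0.
#' @param exponent allometric exponent.
#' @return dimensionless multiplier.
#' @export
allometric_factor <- function(size, reference, exponent) {
  if (any(size <= 0) || any(reference <= 0)) stop("size and reference must be positive")
  if (any(!is.finite(exponent))) stop("exponent must be finite")
  (size / reference)^exponent
}

#' Declare a covariate effect on a structural parameter
#'
#' Two kinds are supported: `"allometric"` (power-law scaling by a body-size
#' descriptor, default fat-free mass) and `"categorical"` (a fractional
#' multiplier applied when a subject-level predicate holds, e.g. a 21%
#' reduction in clearance for HIV-1-positive subjects is `theta = 0.79`).
#'
#' @param param target parameter name (e.g. `"CL"`).
#' @param kind `"allometric"` or `"categorical"`.
#' @param exponent,reference,size allometric settings: exponent, reference
#'   size (kg) and the size descriptor, `"ffm"` (default) or `"weight"`.
#' @param when categorical condition: the name of a logical subject field or
#'   an expression string evaluated in the subject's fields
#'   (e.g. `"art_class == 'pi_lpvr'"`).
#' @param theta categorical multiplier (> 0).
#' @param label short label used in reports; defaults to `when`.
#' @param estimate should `theta` be estimated by [fit_model()]? Allometric
#'   exponents are always fixed.
#' @return an object of class `tbpk_covariate_effect`.
#' @export
covariate_effect <- function(param, kind = c("categorical", "allometric"),
                             exponent = NULL, reference = 45, size = "ffm",
                             when = NULL, theta = NULL, label = NULL,
                             estimate = TRUE) {
  kind <- match.arg(kind)
  if (kind == "allometric") {
    if (is.null(exponent) || !is.finite(exponent)) stop("allometric effect needs a finite exponent")
    if (reference <= 0) stop("reference size must be positive")
    size <- match.arg(size, c("ffm", "weight"))
    eff <- list(param = param, kind = kind, exponent = exponent,
                reference = reference, size = size,
                label = label %||% sprintf("%s~%s^%g", param, size, exponent),
                estimate = FALSE)
  } else {
    if (is.null(when)) stop("categorical effect needs a 'when' predicate")
    if (is.null(theta) || theta <= 0) stop("categorical multiplier theta must be > 0")
    eff <- list(param = param, kind = kind, when = when, theta = theta,
                label = label %||% paste0(param, ":", when), estimate = estimate)
  }
  structure(eff, class = "tbpk_covariate_effect")
}

## Evaluate a categorical predicate for one subject (list of fields)
effect_applies <- function(effect, subject) {
  v <- tryCatch(
    eval(parse(text = effect$when), envir = as.list(subject),
         enclos = baseenv()),
    error = function(e) NA)
  if (length(v) != 1 || is.na(v)) {
    stop(sprintf("covariate '%s' unresolvable for subject %s",
                 effect$when, subject$id %||% "?"))
  }
  isTRUE(as.logical(v))
}

effect_multiplier <- function(effect, subject) {
  if (effect$kind == "allometric") {
    sz <- if (effect$size == "ffm") {
      subject$ffm %||% fat_free_mass(subject$sex, subject$weight, subject$height)
    } else subject$weight
    allometric_factor(sz, effect$reference, effect$exponent)
  } else {
    if (effect_applies(effect, subject)) effect$theta else 1
  }
}

#' Individual typical parameter values for one subject
#'
#' Applies the model's covariate effects to the population typical values:
#' typical value per parameter = population typical x allometric factor x
#' product of applicable categorical multipliers. Application is
#' order-independent (a product of multipliers).
#'
#' @param model a [pk_model_spec()].
#' @param subject a subject, as returned by [subject()] or one row of a
#'   [generate_cohort()] data frame.
#' @return named numeric vector of individual typical parameter values.
#' @examples
#' s <- subject("s1", sex = "male", weight = 51, height = 1.70,
#'              hiv_positive = FALSE)
#' individual_typical_params(rifampin_model(), s)["CL"]  # 25.1 L/h at FFM 45
#' @export
individual_typical_params <- function(model, subject) {
  subject <- as_subject(subject)
  p <- unlist(model$typical)
  for (eff in model$covariates) {
    if (!eff$param %in% names(p)) {
      stop(sprintf("covariate effect targets unknown parameter '%s'", eff$param))
    }
    p[eff$param] <- p[eff$param] * effect_multiplier(eff, subject)
  }
  p
}
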