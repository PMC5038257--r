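## Synthetic cohort generator: virtual subjects with the study's covariate
## structure, WHO weight-band fixed-dose-combination dosing, the intensive
## sampling schedule, and assay LLOQs.

## per-tablet strengths, mg (4-drug fixed-dose combination)
.tablet_mg <- c(rifampin = 150, isoniazid = 75, pyrazinamide = 400, ethambutol = 275)

## assay lower limits of quantification, mg/L
.lloq <- c(rifampin = 0.117, isoniazid = 0.0977, pyrazinamide = 0.200)

## intensive sampling schedule: predose plus 1,2,3,4,6,8 h post dose
.sampling_times <- c(1, 2, 3, 4, 6, 8)

## evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Cohort generator configuration
#'
#' Defaults emulate the study cohort: n = 100, 57% male, 65% HIV-1 positive,
#' 77% of HIV-positive subjects on antiretroviral therapy at the sampling
#' visit, 10% of those on lopinavir/ritonavir. Body size is drawn from
#' sex-specific truncated normal height and BMI distributions calibrated so
#' that, at large n, the cohort medians approximate the reported BMI
#' (21 kg/m2), fat-free mass (45 kg), and age (33 yr) targets; weights below
#' the lowest dosing band (38 kg) are resampled since all study subjects were
#' band-dosed.
#'
#' @param n number of subjects.
#' @param p_male fraction male.
#' @param p_hiv fraction HIV-1 positive.
#' @param p_art_given_hiv fraction of HIV-positive subjects on ART.
#' @param p_lpvr_given_art fraction of ART that is lopinavir/ritonavir based.
#' @param height_mean,height_sd named (`male`, `female`) height parameters, m.
#' @param bmi_mean,bmi_sd BMI distribution parameters, kg/m2.
#' @param age_meanlog,age_sdlog lognormal age parameters (median
#'   `exp(age_meanlog)` yr).
#' @param p_alcohol,p_diabetes,p_prev_inh prevalence of alcohol consumption,
#'   type-2 diabetes, and previous isoniazid treatment.
#' @param seed RNG seed.
#' @return a list of class `tbpk_cohort_config`.
#' @export
cohort_config <- function(n = 100L, p_male = 0.57, p_hiv = 0.65,
                          p_art_given_hiv = 0.77, p_lpvr_given_art = 0.10,
                          height_mean = c(male = 1.69, female = 1.585),
                          height_sd = c(male = 0.068, female = 0.062),
                          bmi_mean = 21.4, bmi_sd = 2.7,
                          age_meanlog = log(33), age_sdlog = 0.24,
                          p_alcohol = 0.37, p_diabetes = 0.04,
                          p_prev_inh = 0.39, seed = NULL) {
  fr <- c(p_male, p_hiv, p_art_given_hiv, p_lpvr_given_art, p_alcohol,
          p_diabetes, p_prev_inh)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  structure(list(n = as.integer(n), p_male = p_male, p_hiv = p_hiv,
                 p_art_given_hiv = p_art_given_hiv,
                 p_lpvr_given_art = p_lpvr_given_art,
                 height_mean = height_mean, height_sd = height_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 age_meanlog = age_meanlog, age_sdlog = age_sdlog,
                 p_alcohol = p_alcohol, p_diabetes = p_diabetes,
                 p_prev_inh = p_prev_inh, seed = seed),
            class = "tbpk_cohort_config")
}

#' Generate a virtual cohort
#'
#' Draws subjects under a [cohort_config()]; deterministic given the seed.
#' Every generated subject satisfies the subject invariants (in particular,
#' only HIV-positive subjects carry an ART class) and weighs at least 38 kg
#' (the lowest WHO dosing band).
#'
#' @param config a [cohort_config()].
#' @return data frame of class `tbpk_cohort`, one row per subject, columns:
#'   `id`, `sex`, `weight`, `height`, `ffm`, `bmi`, `hiv_positive`,
#'   `art_class`, `age`, `albumin`, `total_protein`, `cd4`, `cd4_lt200`,
#'   `alcohol`, `diabetes`, `prev_inh`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "tbpk_cohort_config"))
  with_seed(config$seed, {
    n <- config$n
    sex <- ifelse(runif(n) < config$p_male, "male", "female")
    height <- rtruncnorm(n, config$height_mean[sex], config$height_sd[sex],
                         1.45, 1.95)
    ## resample BMI until every implied weight clears the 38 kg dosing floor
    weight <- rep(0, n)
    for (it in 1:200) {
      low <- weight < 38
      if (!any(low)) break
      bmi <- rtruncnorm(sum(low), config$bmi_mean, config$bmi_sd, 15.5, 32)
      weight[low] <- bmi * height[low]^2
    }
    weight <- pmax(weight, 38)
    hiv <- runif(n) < config$p_hiv
    art <- rep("none", n)
    on_art <- hiv & runif(n) < config$p_art_given_hiv
    art[on_art] <- ifelse(runif(sum(on_art)) < config$p_lpvr_given_art,
                          "pi_lpvr", "nnrti")
    age <- pmin(pmax(exp(rnorm(n, config$age_meanlog, config$age_sdlog)), 18), 70)
    albumin <- rtruncnorm(n, 37.5, 4.4, 20, 55)
    total_protein <- rtruncnorm(n, 85.5, 9.6, 55, 120)
    cd4 <- ifelse(hiv, exp(rnorm(n, log(233), 0.958)), NA_real_)
    cohort <- data.frame(
      id = sprintf("S%03d", seq_len(n)), sex = sex, weight = weight,
      height = height, ffm = fat_free_mass(sex, weight, height),
      bmi = weight / height^2, hiv_positive = hiv, art_class = art,
      age = age, albumin = albumin, total_protein = total_protein,
      cd4 = cd4, cd4_lt200 = !is.na(cd4) & cd4 < 200,
      alcohol = runif(n) < config$p_alcohol,
      diabetes = runif(n) < config$p_diabetes,
      prev_inh = runif(n) < config$p_prev_inh,
      stringsAsFactors = FALSE)
    class(cohort) <- c("tbpk_cohort", "data.frame")
    cohort
  })
}

#' WHO weight-band fixed-dose-combination dose
#'
#' Band boundaries (upper bounds inclusive): 38-55 kg get 3 tablets,
#' 55-70 kg (exclusive lower) get 4, and above 70 kg get 5. Each tablet contains 150 mg
#' rifampin, 75 mg isoniazid, 400 mg pyrazinamide, and 275 mg ethambutol
#' (ethambutol is dosed but not modelled). Weights below 38 kg are outside
#' the band table and rejected.
#'
#' @param weight body weight, kg (>= 38).
#' @return list with `tablets` and `mg` (named per-drug dose, mg).
#' @export
assign_who_band_dose <- function(weight) {
  if (length(weight) != 1 || !is.finite(weight)) stop("weight must be a single number")
  if (weight < 38) stop("weight ", weight, " kg is below the lowest dosing band (38 kg)")
  tablets <- if (weight <= 55) 3L else if (weight <= 70) 4L else 5L
  list(tablets = tablets, mg = .tablet_mg * tablets)
}

#' Build one subject's dosing and sampling design
#'
#' One steady-state predose observation, the observed dose at time 0, and
#' post-dose observations at 1, 2, 3, 4, 6, and 8 h (7 observation records
#' per drug), with the drug's assay LLOQ attached. The predose record carries
#' `occasion = "predose"`; post-dose records carry `occasion = "intensive"`.
#'
#' @param subj a subject (see [subject()] / [generate_cohort()]).
#' @param drug `"rifampin"`, `"isoniazid"`, or `"pyrazinamide"`.
#' @return an event-table data frame (see [read_event_table()]) without
#'   concentration values (`dv` is `NA`; fill by simulation or assay).
#' @export
build_design <- function(subj, drug = c("rifampin", "isoniazid", "pyrazinamide")) {
  drug <- match.arg(drug)
  subj <- as_subject(subj)
  dose <- assign_who_band_dose(subj$weight)$mg[[drug]]
  lloq <- .lloq[[drug]]
  rows <- rbind(
    data.frame(id = subj$id, time = 0, evid = 0L, amt = NA_real_,
               dv = NA_real_, blq = FALSE, lloq = lloq, occasion = "predose",
               drug = drug, stringsAsFactors = FALSE),
    data.frame(id = subj$id, time = 0, evid = 1L, amt = dose, dv = NA_real_,
               blq = FALSE, lloq = NA_real_, occasion = "intensive",
               drug = drug, stringsAsFactors = FALSE),
    data.frame(id = subj$id, time = .sampling_times, evid = 0L,
               amt = NA_real_, dv = NA_real_, blq = FALSE, lloq = lloq,
               occasion = "intensive", drug = drug, stringsAsFactors = FALSE)
  )
  attach_subject_covariates(rows, subj)
}

## carry subject covariates along event-table rows
attach_subject_covariates <- function(rows, subj) {
  rows$sex <- subj$sex; rows$weight <- subj$weight; rows$height <- subj$height
  rows$hiv_positive <- subj$hiv_positive; rows$art_class <- subj$art_class
  for (nm in c("age", "albumin", "total_protein", "alcohol", "diabetes", "prev_inh")) {
    if (!is.null(subj[[nm]])) rows[[nm]] <- subj[[nm]]
  }
  rows
}

#' Simulate binary side-effect outcomes from exposure quartiles
#'
#' Bernoulli outcomes from a logistic model on exposure quartile membership:
#' the intercept is solved so the expected prevalence matches `prevalence`
#' (default 35%, the reported fraction with grade 1-2 side effects), and the
#' quartile log-odds-ratios default to the reported unadjusted odds ratios
#' (Q2 1.26, Q3 1.88, Q4 7.11 vs Q1).
#'
#' @param exposures per-subject exposure metric (e.g. isoniazid AUC0-24).
#' @param or_quartile odds ratios for quartiles 1-4 (first must be 1).
#' @param prevalence target marginal outcome prevalence.
#' @param seed RNG seed.
#' @return list with `outcome` (logical vector), `quartile` (integer), and
#'   `intercept` (the solved log-odds intercept).
#' @export
generate_side_effect_outcomes <- function(exposures,
                                          or_quartile = c(1, 1.26, 1.88, 7.11),
                                          prevalence = 0.35, seed = NULL) {
  if (length(or_quartile) != 4 || or_quartile[1] != 1 || any(or_quartile <= 0)) {
    stop("or_quartile must be 4 positive odds ratios with the first equal to 1")
  }
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  q <- quartile_assign(exposures)
  off <- log(or_quartile)[q]
  b0 <- uniroot(function(b) mean(plogis(b + off)) - prevalence,
                c(-20, 20), tol = 1e-10)$root
  p <- plogis(b0 + off)
  outcome <- with_seed(seed, runif(length(p)) < p)
  list(outcome = outcome, quartile = q, intercept = b0)
}
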