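## Shared fixtures: small cohorts, designs, and simulated datasets built in
## code at test time.

small_cohort <- function(n = 6, seed = 42) {
  generate_cohort(cohort_config(n = n, seed = seed))
}

## two hand-built subjects with known covariates
two_subjects <- function() {
  list(
    subject("A", "male", 51, 1.70, hiv_positive = FALSE,
            age = 33, albumin = 38, alcohol = FALSE, diabetes = FALSE,
            prev_inh = FALSE),
    subject("B", "female", 60, 1.60, hiv_positive = TRUE, art_class = "nnrti",
            age = 41, albumin = 35, alcohol = TRUE, diabetes = FALSE,
            prev_inh = TRUE)
  )
}

## a valid miniature event table (2 subjects, rifampin design)
tiny_event_table <- function() {
  rows <- do.call(rbind, lapply(two_subjects(), build_design, drug = "rifampin"))
  obs <- rows$evid == 0 & rows$occasion == "intensive"
  rows$dv[obs] <- round(runif(sum(obs), 0.5, 8), 3)
  pre <- rows$evid == 0 & rows$occasion == "predose"
  rows$dv[pre] <- NA
  rows$blq[pre] <- TRUE
  validate_event_table(rows)
}

## simulated rifampin dataset under the study design
sim_rif_data <- function(n = 20, cohort_seed = 11, obs_seed = 12,
                         model = rifampin_model()) {
  coh <- generate_cohort(cohort_config(n = n, seed = cohort_seed))
  simulate_observations(model, coh, seed = obs_seed)
}

## reduced random-effect specification used for Laplace fitting exercises
## (drops nothing for the compiled hybrid path; kept for readability)
rif_fit_start <- function() {
  list(CL = 25.1 * 1.4, V = 56.4 * 0.75,
       omega2_iiv_CL = 2 * cv_to_omega2(34.3))
}
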