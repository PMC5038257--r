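## Random-effect mapping, residual error, and the censored (M3) likelihood.

test_that("individual parameters: identity, doubling, %CV round trip", {
  typ <- c(CL = 25.1, V = 56.4)
  expect_equal(individual_params(typ, c(CL = 0), c(V = 0)), typ)
  expect_equal(individual_params(typ, c(CL = log(2)))[["CL"]], 50.2)
  ## %CV <-> variance conversion: 34.3 %CV and the rifampin F IOV 29.1 %CV
  expect_equal(omega2_to_cv(cv_to_omega2(34.3)), 34.3)
  expect_equal(cv_to_omega2(29.1), log(1 + 0.291^2))
  expect_equal(omega2_to_cv(0.0812927), 29.1, tolerance = 1e-4)
  ## the simpler sd convention round-trips too
  expect_equal(omega2_to_cv(cv_to_omega2(50, "sd"), "sd"), 50)
  expect_error(individual_params(typ, c(XX = 0.1)), "named")
})

test_that("combined residual error behaves at its limits", {
  expect_identical(residual_sd(0, 0.196, 0.15), 0.196)
  expect_identical(residual_sd(10, 0, 0.13), 1.3)
  ## rifampin error model at pred = 10 mg/L
  expect_equal(residual_sd(10, 0.196, 0.15), sqrt(0.196^2 + 1.5^2),
               tolerance = 1e-10)
  expect_error(residual_sd(-1, 0.1, 0.1), ">= 0")
})

test_that("M3 censored likelihood: limits, symmetry, Gaussian reduction", {
  ## prediction far below the LLOQ: probability of censoring ~ 1
  expect_gt(obs_loglik(NA, 0.001, 0.2, lloq = 5, blq = TRUE), -1e-6)
  ## prediction at the LLOQ: exactly half the mass is censored
  expect_equal(obs_loglik(NA, 0.117, 0.3, lloq = 0.117, blq = TRUE), log(0.5))
  ## uncensored observation is the plain Gaussian density
  expect_equal(obs_loglik(4.2, 5, 0.8, blq = FALSE),
               dnorm(4.2, 5, 0.8, log = TRUE))
  expect_error(obs_loglik(NA, 1, -0.1, blq = FALSE), "positive")
  expect_error(obs_loglik(NA, 1, 0.5, lloq = NA, blq = TRUE), "LLOQ")
})

test_that("censored contribution decreases monotonically in the prediction", {
  preds <- seq(0, 2, by = 0.1)
  ll <- obs_loglik(rep(NA, length(preds)), preds, 0.3, lloq = 0.5,
                   blq = rep(TRUE, length(preds)))
  expect_true(all(diff(ll) < 0))
})

test_that("subject conditional log-likelihood sums per-point contributions", {
  m <- rifampin_model()
  reg <- dose_regimen(600)
  p <- unlist(m$typical)
  obs <- data.frame(time = c(1, 2, 4), dv = c(5.1, 6.0, 3.2),
                    blq = FALSE, lloq = 0.117, occasion = "intensive")
  ll <- subject_conditional_loglik(obs, m, p, reg)
  ## brute-force per-point oracle
  pred <- conc_one_cpt_lag(obs$time, 600, 1, p[["CL"]], p[["V"]], p[["ka"]],
                           p[["tlag"]])
  manual <- sum(dnorm(obs$dv, pred, residual_sd(pred, 0.196, 0.15),
                      log = TRUE))
  expect_equal(ll, manual, tolerance = 1e-10)
  ## additivity: duplicating an observation doubles its contribution
  ll2 <- subject_conditional_loglik(obs[c(1, 1, 2, 3), ], m, p, reg)
  expect_equal(ll2 - ll, ll - subject_conditional_loglik(obs[2:3, ], m, p, reg),
               tolerance = 1e-10)
  ## zero observations contribute zero
  expect_identical(subject_conditional_loglik(obs[0, ], m, p, reg), 0)
})

test_that("predose records are evaluated on the steady-state profile", {
  m <- rifampin_model()
  reg <- dose_regimen(600)
  p <- unlist(m$typical)
  obs <- data.frame(time = 0, dv = NA, blq = TRUE, lloq = 0.117,
                    occasion = "predose")
  ll <- subject_conditional_loglik(obs, m, p, reg)
  pred_ss <- steady_state_conc(24, reg, function(t)
    conc_one_cpt_lag(t, 600, 1, p[["CL"]], p[["V"]], p[["ka"]], p[["tlag"]]))
  expect_equal(ll, pnorm((0.117 - pred_ss) / residual_sd(pred_ss, 0.196, 0.15),
                         log.p = TRUE), tolerance = 1e-10)
})

test_that("with no BLQ flags the M3 likelihood is the uncensored Gaussian one", {
  m <- rifampin_model()
  dat <- sim_rif_data(n = 6)
  obs <- dat[dat$evid == 0 & !dat$blq & !is.na(dat$dv) &
               dat$occasion == "intensive" & dat$id == dat$id[1], ]
  p <- unlist(m$typical)
  reg <- dose_regimen(450)
  ll <- subject_conditional_loglik(obs, m, p, reg)
  pred <- conc_one_cpt_lag(obs$time, 450, 1, p[["CL"]], p[["V"]], p[["ka"]],
                           p[["tlag"]])
  expect_equal(ll, sum(dnorm(obs$dv, pred,
                             residual_sd(pred, 0.196, 0.15), log = TRUE)),
               tolerance = 1e-10)
})

test_that("mixture likelihood collapses and marginalises correctly", {
  m <- isoniazid_model()
  reg <- dose_regimen(300)
  p <- unlist(m$typical)
  obs <- data.frame(time = c(1, 3), dv = c(3.0, 1.4), blq = FALSE,
                    lloq = 0.0977, occasion = "intensive")
  base <- subject_conditional_loglik(obs, m, p, reg)
  ## identical components collapse to the single-component value
  mx1 <- mixture_spec("CL", c(1, 1), c(0.4, 0.6))
  expect_equal(mixture_conditional_loglik(obs, m, p, reg, mx1), base,
               tolerance = 1e-10)
  ## pi = (1, 0) gives component 1 exactly
  mx2 <- mixture_spec("CL", c(1, 2.5), c(1, 0))
  expect_equal(mixture_conditional_loglik(obs, m, p, reg, mx2), base,
               tolerance = 1e-10)
  ## two distinct components: direct log-sum-exp oracle
  mx3 <- mixture_spec("CL", c(0.6, 2.0), c(0.3, 0.7))
  p2 <- p; p2["CL"] <- p[["CL"]] * 0.6
  p3 <- p; p3["CL"] <- p[["CL"]] * 2.0
  direct <- log(0.3 * exp(subject_conditional_loglik(obs, m, p2, reg)) +
                  0.7 * exp(subject_conditional_loglik(obs, m, p3, reg)))
  expect_equal(mixture_conditional_loglik(obs, m, p, reg, mx3), direct,
               tolerance = 1e-8)
})

test_that("compiled and R joint densities agree for the lag model", {
  m <- rifampin_model()
  dat <- sim_rif_data(n = 4)
  obj_cpp <- tbpk:::build_objective(dat, m, fit_settings(lag_quadrature = 0,
                                                         ka_quadrature = 0))
  obj_r <- tbpk:::build_objective(dat, m, fit_settings(use_compiled = FALSE,
                                                       lag_quadrature = 0,
                                                       ka_quadrature = 0))
  up <- obj_cpp$unpack(obj_cpp$pack$x0)
  om2 <- obj_cpp$eta_omega2(up)
  set.seed(3)
  for (i in 1:4) {
    eta <- rnorm(obj_cpp$d, 0, 0.3)
    jc <- obj_cpp$joint_fn(i, up, om2)(eta)
    jr <- obj_r$joint_fn(i, up, om2)(eta)
    expect_equal(jc, jr, tolerance = 1e-8)
  }
})
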