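## Laplace estimation machinery against quadrature, importance-sampling and
## closed-form oracles on deliberately small problems.

## a smooth small specification: clearance IIV only, no absorption effects,
## and no lopinavir/ritonavir covariate (its stratum is usually empty in the
## miniature cohorts used here)
smooth_model <- function(omega_cl = cv_to_omega2(34.3), a = 0.196, b = 0.15) {
  m <- rifampin_model()
  m <- set_random_effects(m, iiv = c(CL = omega_cl), iov = numeric())
  m <- set_covariates(m, drop = "LPV/r on CL")
  m$error <- list(a = a, b = b)
  m
}

test_that("noiseless data return the generating typical values", {
  m0 <- smooth_model(omega_cl = 0, a = 1e-3, b = 0)
  m0 <- set_random_effects(m0, iiv = numeric())
  ## keep only the allometric effects: a tiny cohort can lack one HIV
  ## stratum, leaving clearance and the HIV multiplier jointly unidentified
  m0 <- set_covariates(m0, covariates = Filter(
    function(e) e$kind == "allometric", m0$covariates))
  coh <- small_cohort(n = 5, seed = 51)
  dat <- simulate_observations(m0, coh, seed = 52)
  fit <- fit_model(dat, m0, fit_settings(
    estimate_error = FALSE,
    start = list(CL = 30, V = 48, ka = 1.5, tlag = 0.5)))
  est <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  expect_lt(abs(est[["CL"]] / 25.1 - 1), 0.01)
  expect_lt(abs(est[["V"]] / 56.4 - 1), 0.01)
  expect_lt(abs(est[["ka"]] / 1.21 - 1), 0.01)
  expect_true(fit$convergence$converged)
})

test_that("Laplace OFV matches 51-node adaptive quadrature on a toy model", {
  ## conjugate-like toy: modest variability and near-additive error keep the
  ## conditional posterior close to Gaussian, where Laplace is exact
  m <- smooth_model(omega_cl = cv_to_omega2(20), a = 0.1, b = 0.02)
  coh <- small_cohort(n = 4, seed = 53)
  dat <- simulate_observations(m, coh, seed = 54)
  fit <- fit_model(dat, m, fit_settings(outer_iter = 0, outer_restarts = 0))
  agq <- ofv_agq(fit, nodes = 51)
  expect_lt(abs(fit$ofv - agq), 0.01)
})

test_that("importance sampling agrees with quadrature and scales as 1/sqrt(n)", {
  m <- smooth_model(omega_cl = cv_to_omega2(20), a = 0.1, b = 0.02)
  coh <- small_cohort(n = 4, seed = 53)
  dat <- simulate_observations(m, coh, seed = 54)
  fit <- fit_model(dat, m, fit_settings(outer_iter = 0, outer_restarts = 0))
  agq <- ofv_agq(fit, nodes = 51)
  is1 <- ofv_importance_sampling(fit, n_samples = 2000, seed = 5)
  expect_lt(abs(is1$ofv - agq), 3 * max(is1$mc_se, 1e-6))
  ## quadrupling the sample halves the Monte-Carlo SE (allow slack)
  is4 <- ofv_importance_sampling(fit, n_samples = 8000, seed = 5)
  expect_lt(is4$mc_se, is1$mc_se)
  expect_gt(is1$mc_se / is4$mc_se, 1.3)
})

test_that("with no random effects the IS OFV equals the conditional OFV", {
  m0 <- smooth_model()
  m0 <- set_random_effects(m0, iiv = numeric())
  coh <- small_cohort(n = 3, seed = 55)
  dat <- simulate_observations(m0, coh, seed = 56)
  fit <- fit_model(dat, m0, fit_settings(outer_iter = 0, outer_restarts = 0))
  is0 <- ofv_importance_sampling(fit, seed = 1)
  expect_identical(is0$ofv, fit$ofv)
  expect_identical(is0$mc_se, 0)
})

test_that("compiled and R estimation paths give the same OFV", {
  m <- smooth_model()
  coh <- small_cohort(n = 3, seed = 57)
  dat <- simulate_observations(m, coh, seed = 58)
  f_cpp <- fit_model(dat, m, fit_settings(outer_iter = 0, outer_restarts = 0))
  f_r <- fit_model(dat, m, fit_settings(outer_iter = 0, outer_restarts = 0,
                                        use_compiled = FALSE))
  expect_equal(f_cpp$ofv, f_r$ofv, tolerance = 1e-5)
})

test_that("empirical Bayes estimates: prior mode without data, stationarity", {
  m <- smooth_model()
  coh <- small_cohort(n = 4, seed = 59)
  dat <- simulate_observations(m, coh, seed = 60)
  ## subject 1 loses all observations (kept as dose-only record set)
  dat2 <- dat[!(dat$id == dat$id[1] & dat$evid == 0), ]
  fit <- fit_model(dat2, m, fit_settings(outer_iter = 0, outer_restarts = 0))
  ebe <- empirical_bayes(fit)
  expect_equal(ebe$iiv_CL[1], 0, tolerance = 1e-6)
  ## gradient of each subject's joint density vanishes at the reported mode
  obj <- fit$.obj
  up <- obj$unpack(fit$par)
  om2 <- obj$eta_omega2(up)
  for (i in 2:3) {
    joint <- obj$joint_fn(i, up, om2)
    g <- tbpk:::num_gradient(joint, ebe$iiv_CL[i])
    expect_lt(abs(g), 1e-2)
  }
})

test_that("near-zero residual error makes EBEs reproduce the simulated effects", {
  m <- smooth_model(a = 0.005, b = 0.001)
  coh <- small_cohort(n = 6, seed = 61)
  true_eta <- tbpk:::with_seed(62, tbpk:::draw_random_effects(m, 6))
  dat <- simulate_observations(m, coh, seed = 62)
  fit <- fit_model(dat, m, fit_settings(outer_iter = 0, outer_restarts = 0))
  expect_equal(unname(empirical_bayes(fit)$iiv_CL),
               unname(true_eta[, "iiv_CL"]), tolerance = 0.02)
})

test_that("shrinkage edge cases and design dependence", {
  expect_equal(shrinkage(rep(0, 10), 0.3), 100)
  set.seed(63)
  x <- rnorm(2000, 0, 0.3)
  expect_equal(shrinkage(x, sd(x)), 0, tolerance = 1e-8)
  expect_true(is.na(shrinkage(rnorm(5), 0)))
  ## rich sampling shrinks little on CL; a two-point design shrinks more
  m <- smooth_model()
  coh <- small_cohort(n = 12, seed = 64)
  dat <- simulate_observations(m, coh, seed = 65)
  fit_rich <- fit_model(dat, m, fit_settings(outer_iter = 0, outer_restarts = 0))
  sparse <- dat[dat$evid == 1 | dat$time %in% c(0, 2), ]
  fit_sparse <- fit_model(sparse, m, fit_settings(outer_iter = 0,
                                                  outer_restarts = 0))
  expect_lt(fit_rich$shrinkage[["iiv_CL"]], 15)
  expect_gt(fit_sparse$shrinkage[["iiv_CL"]], fit_rich$shrinkage[["iiv_CL"]])
})

test_that("fit is invariant to subject order and relabeling", {
  m <- smooth_model()
  coh <- small_cohort(n = 5, seed = 66)
  dat <- simulate_observations(m, coh, seed = 67)
  perm <- dat[order(match(dat$id, rev(unique(dat$id)))), ]
  relab <- dat
  relab$id <- paste0("zz_", relab$id)
  st <- fit_settings(outer_iter = 40)
  f1 <- fit_model(dat, m, st)
  f2 <- fit_model(perm, m, st)
  f3 <- fit_model(relab, m, st)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-6)
  expect_equal(f1$ofv, f3$ofv, tolerance = 1e-6)
  expect_equal(f1$estimates$estimate, f3$estimates$estimate, tolerance = 1e-6)
})

test_that("non-convergence is flagged, never silent", {
  m <- smooth_model()
  coh <- small_cohort(n = 4, seed = 68)
  dat <- simulate_observations(m, coh, seed = 69)
  f <- fit_model(dat, m, fit_settings(outer_iter = 1, outer_restarts = 0,
                                      start = list(CL = 250, V = 5)))
  expect_false(f$convergence$converged)
})

test_that("adding a truly present covariate effect lowers the OFV", {
  m <- rifampin_model()  # generating model carries the HIV effect
  coh <- generate_cohort(cohort_config(n = 30, seed = 70))
  dat <- simulate_observations(m, coh, seed = 71)
  base <- smooth_model()
  base <- set_covariates(base, covariates = Filter(
    function(e) e$kind == "allometric", base$covariates))
  with_hiv <- set_covariates(base, add = covariate_effect(
    "CL", "categorical", when = "hiv_positive", theta = 1, label = "HIV"))
  st <- fit_settings(outer_iter = 120)
  f0 <- fit_model(dat, base, st)
  f1 <- fit_model(dat, with_hiv, st)
  expect_lte(f1$ofv, f0$ofv + 1e-6)
})

test_that("Fisher-information CIs behave sanely and tighten with n", {
  m <- smooth_model()
  st <- fit_settings(outer_iter = 150)
  widths <- vapply(c(12, 48), function(n) {
    coh <- small_cohort(n = n, seed = 72)
    dat <- simulate_observations(m, coh, seed = 73)
    fit <- fit_model(dat, m, st)
    prec <- fisher_precision(fit)
    expect_true(all(prec$lower <= prec$estimate & prec$estimate <= prec$upper,
                    na.rm = TRUE))
    cl <- prec[prec$parameter == "CL", ]
    log(cl$upper / cl$lower)
  }, numeric(1))
  ## quadrupling n should halve the CI width, within generous slack
  expect_gt(widths[1] / widths[2], 1.4)
})

test_that("confidence intervals cover the generating value at nominal rate", {
  ## 20 replicates of a small design; CL coverage should be near 95%
  m <- smooth_model()
  st <- fit_settings(outer_iter = 120)
  hits <- vapply(1:20, function(r) {
    coh <- small_cohort(n = 14, seed = 400 + r)
    dat <- simulate_observations(m, coh, seed = 500 + r)
    fit <- fit_model(dat, m, st)
    prec <- fisher_precision(fit)
    cl <- prec[prec$parameter == "CL", ]
    !is.na(cl$lower) && cl$lower <= 25.1 && 25.1 <= cl$upper
  }, logical(1))
  expect_gte(100 * mean(hits), 80)
})
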