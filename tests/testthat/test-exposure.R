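## Exposure metrics, LLOQ-censored simulation, and visual predictive checks.

test_that("steady-state AUC equals F*dose/CL and scales with clearance", {
  m <- rifampin_model()
  p <- unlist(m$typical)
  reg <- dose_regimen(600)
  met <- exposure_metrics(m, p, reg)
  expect_equal(met$auc24, 600 / 25.1)            # 23.90 mg.h/L
  expect_equal(met$auc24, met$auc24_trapz, tolerance = 5e-3)
  ## doubling CL halves the AUC
  p2 <- p; p2["CL"] <- p[["CL"]] * 2
  expect_equal(exposure_metrics(m, p2, reg)$auc24, met$auc24 / 2)
})

test_that("analytic and trapezoidal AUC agree for all three drugs", {
  for (m in list(rifampin_model(), isoniazid_model(), pyrazinamide_model())) {
    dose <- c(rifampin = 600, isoniazid = 300, pyrazinamide = 1600)[[m$drug]]
    met <- exposure_metrics(m, unlist(m$typical), dose_regimen(dose),
                            grid_step = if (m$drug == "rifampin") 0.01 else 0.1)
    expect_lt(abs(met$auc24_trapz - met$auc24) / met$auc24, 0.005)
  }
})

test_that("grid Cmax is within 0.1% of a fine-grid oracle and phase-stable", {
  m <- rifampin_model()
  p <- unlist(m$typical)
  reg <- dose_regimen(600)
  met <- exposure_metrics(m, p, reg, grid_step = 0.01)
  fine <- exposure_metrics(m, p, reg, grid_step = 0.001, refine = FALSE)
  expect_equal(met$cmax, fine$cmax, tolerance = 1e-3)
  ## shifting the grid phase by half a step moves Cmax by <0.1%
  grid1 <- seq(0, 24, by = 0.01)
  grid2 <- pmin(grid1 + 0.005, 24)
  c1 <- max(tbpk:::ss_profile(m, p, reg, grid1))
  c2 <- max(tbpk:::ss_profile(m, p, reg, grid2))
  expect_lt(abs(c1 - c2) / c1, 1e-3)
  expect_true(met$tmax >= 0 && met$tmax < 24)
})

test_that("low-exposure flags use strict thresholds per drug", {
  met <- data.frame(drug = c("rifampin", "rifampin", "isoniazid",
                             "pyrazinamide"),
                    cmax = c(7.99, 8.0, 4.42, 34.9))
  out <- flag_low_exposure(met)
  expect_identical(out$low_cmax, c(TRUE, FALSE, FALSE, TRUE))
  ## thresholds are configurable (e.g. the 30 mg/L pyrazinamide variant)
  out2 <- flag_low_exposure(met, c(rifampin = 8, isoniazid = 3,
                                   pyrazinamide = 30))
  expect_false(out2$low_cmax[4])
  expect_error(flag_low_exposure(data.frame(drug = "ethambutol", cmax = 1)),
               "no threshold")
})

test_that("simulation is deterministic at zero variability and censors BLQ", {
  m <- rifampin_model()
  m0 <- set_random_effects(m, iiv = numeric(), iov = numeric())
  m0$error <- list(a = 1e-9, b = 0)
  coh <- small_cohort(n = 3, seed = 6)
  sim <- simulate_observations(m0, coh, seed = 1)
  obs <- sim[sim$evid == 0 & sim$occasion == "intensive", ]
  for (sid in unique(obs$id)) {
    rows <- obs[obs$id == sid, ]
    subj <- coh[coh$id == sid, ]
    typ <- individual_typical_params(m, subj)
    pred <- conc_one_cpt_lag(rows$time, assign_who_band_dose(subj$weight)$mg[["rifampin"]],
                             1, typ[["CL"]], typ[["V"]], typ[["ka"]], typ[["tlag"]])
    keep <- !rows$blq
    expect_equal(rows$dv[keep], pred[keep], tolerance = 1e-5)
    expect_true(all(pred[rows$blq] < 0.117))
  }
  ## BLQ rows carry no concentration
  expect_true(all(is.na(sim$dv[sim$blq])))
})

test_that("simulated clearance variability matches the specified IIV", {
  m <- rifampin_model()
  E <- tbpk:::with_seed(99, tbpk:::draw_random_effects(m, 10000))
  cv_emp <- 100 * sd(exp(E[, "iiv_CL"])) / mean(exp(E[, "iiv_CL"]))
  expect_lt(abs(cv_emp - 34.3) / 34.3, 0.02)
})

test_that("vpc: degenerate bands at nsim=1, strata partition observations", {
  m <- rifampin_model()
  coh <- small_cohort(n = 8, seed = 21)
  dat <- simulate_observations(m, coh, seed = 22)
  v1 <- vpc(m, dat, nsim = 1, seed = 5)
  expect_true(all(v1$bins$lo == v1$bins$hi, na.rm = TRUE))
  v2 <- vpc(m, dat, nsim = 8, strata = "hiv_positive", seed = 5)
  counts <- table(v2$bins$stratum) / length(v2$percentiles)
  obs_rows <- dat[dat$evid == 0 & (dat$blq | !is.na(dat$dv)), ]
  expect_equal(sum(v2$bins$stratum == "TRUE") > 0 ||
                 sum(v2$bins$stratum == "FALSE") > 0, TRUE)
  ## each observation lands in exactly one stratum bin set
  expect_equal(length(unique(obs_rows$id)),
               length(unique(obs_rows$id[obs_rows$hiv_positive])) +
                 length(unique(obs_rows$id[!obs_rows$hiv_positive])))
})

test_that("vpc bands widen as residual error grows", {
  coh <- small_cohort(n = 10, seed = 31)
  m <- rifampin_model()
  dat <- simulate_observations(m, coh, seed = 32)
  widths <- vapply(c(0.05, 0.15, 0.4), function(b) {
    mb <- m; mb$error$b <- b
    v <- vpc(mb, dat, nsim = 30, seed = 33)
    mid <- v$bins[v$bins$percentile == 50 & v$bins$occasion == "intensive", ]
    mean(mid$hi - mid$lo)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("per-subject exposures carry band doses and positive metrics", {
  m <- rifampin_model()
  coh <- small_cohort(n = 5, seed = 41)
  ex <- simulate_exposures(m, coh, seed = 42)
  expect_equal(nrow(ex), 5)
  expect_true(all(ex$cmax > 0 & ex$auc24 > 0))
  expect_true(all(ex$tmax >= 0 & ex$tmax < 24))
  expect_equal(ex$dose,
               vapply(coh$weight, function(w)
                 assign_who_band_dose(w)$mg[["rifampin"]], numeric(1)))
  fl <- flag_low_exposure(ex)
  expect_type(fl$low_cmax, "logical")
})
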