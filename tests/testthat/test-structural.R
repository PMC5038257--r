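## Structural models against independent oracles: numerical ODE integration
## (deSolve), quadrature mass balance, and closed-form limits.

test_that("one-compartment lag model: zero before lag, mass balance", {
  expect_identical(conc_one_cpt_lag(c(0, 0.3, 0.691), 600, 1, 25.1, 56.4,
                                    1.21, 0.691),
                   c(0, 0, 0))
  ## integral of CL * C(t) over (0, Inf) returns the absorbed dose
  mb <- integrate(function(t) conc_one_cpt_lag(t, 600, 1, 25.1, 56.4, 1.21,
                                               0.691) * 25.1,
                  0, Inf, rel.tol = 1e-10)$value
  expect_equal(mb, 600, tolerance = 1e-6)
})

test_that("one-compartment lag model matches an ODE oracle", {
  skip_if_not_installed("deSolve")
  pars <- c(ka = 1.21, CL = 25.1, V = 56.4, tlag = 0.691)
  rhs <- function(t, y, p) {
    list(c(-p[["ka"]] * y[1], p[["ka"]] * y[1] - p[["CL"]] / p[["V"]] * y[2]))
  }
  times <- c(0, 0.75, 1, 2, 3, 4, 6, 8, 12)
  ## start the depot at the lag time
  out <- deSolve::ode(c(600, 0), c(pars[["tlag"]], times[times > pars[["tlag"]]]),
                      rhs, pars, rtol = 1e-10, atol = 1e-12)
  ode_conc <- out[-1, 3] / pars[["V"]]
  ana <- conc_one_cpt_lag(times[times > pars[["tlag"]]], 600, 1, 25.1, 56.4,
                          1.21, 0.691)
  expect_equal(ana, unname(ode_conc), tolerance = 1e-3 * 0.1)  # <0.1%
})

test_that("equal absorption/elimination rates use the limiting form", {
  ke <- 25.1 / 56.4
  v1 <- conc_one_cpt_lag(2, 600, 1, 25.1, 56.4, ke * (1 + 1e-7), 0)
  v2 <- conc_one_cpt_lag(2, 600, 1, 25.1, 56.4, ke * (1 + 1e-4), 0)
  expect_equal(v1, v2, tolerance = 1e-3)
  expect_true(is.finite(v1) && v1 > 0)
})

test_that("transit input: conservation, first-order reduction", {
  tot <- integrate(function(t) transit_input_rate(t, 300, 1, 0.32, 2.04),
                   0, Inf, rel.tol = 1e-10)$value
  expect_equal(tot, 300, tolerance = 1e-7)
  ## NN = 0 reduces to first-order input with rate 1/MTT
  t <- c(0.1, 0.5, 1, 2)
  expect_equal(transit_input_rate(t, 100, 1, 0.5, 0),
               100 * 2 * exp(-2 * t), tolerance = 1e-10)
})

test_that("continuous transit profile is bracketed by integer-chain ODEs", {
  skip_if_not_installed("deSolve")
  ## chain with integer NN transit compartments, then depot, then central
  chain_ode <- function(NN, t_out, dose = 300, MTT = 0.32, ka = 1.2,
                        CL = 26, V = 31.9, Q = 12.6, Vp = 21.4) {
    ktr <- (NN + 1) / MTT
    rhs <- function(t, y, p) {
      nt <- NN + 1  # transit states
      d <- numeric(nt + 3)
      d[1] <- -ktr * y[1]
      if (nt > 1) for (i in 2:nt) d[i] <- ktr * (y[i - 1] - y[i])
      d[nt + 1] <- ktr * y[nt] - ka * y[nt + 1]              # depot
      d[nt + 2] <- ka * y[nt + 1] - (CL / V + Q / V) * y[nt + 2] +
        (Q / Vp) * y[nt + 3]                                  # central
      d[nt + 3] <- (Q / V) * y[nt + 2] - (Q / Vp) * y[nt + 3] # peripheral
      list(d)
    }
    y0 <- c(dose, numeric(NN + 3))
    out <- deSolve::ode(y0, c(0, t_out), rhs, NULL, rtol = 1e-10, atol = 1e-12)
    out[-1, NN + 4] / V  # column 1 is time; central is state NN+3
  }
  t_out <- c(0.5, 1, 2, 4)
  p <- unlist(isoniazid_model()$typical)
  cont <- conc_two_cpt_transit(t_out, 300, p)  # NN = 2.04
  lo <- chain_ode(2, t_out)
  hi <- chain_ode(3, t_out)
  ## the continuous NN=2.04 profile lies between the NN=2 and NN=3 chains
  expect_true(all(cont <= pmax(lo, hi) + 1e-9 & cont >= pmin(lo, hi) - 1e-9))
  ## and sits much nearer the NN=2 chain
  expect_equal(cont, lo, tolerance = 0.06)
})

test_that("two-compartment transit model: t=0, Q->0 limit, mass balance", {
  p <- unlist(isoniazid_model()$typical)
  expect_identical(conc_two_cpt_transit(0, 300, p), 0)
  ## Q -> 0 reduces to the one-compartment transit model
  p0 <- p; p0["Q"] <- 1e-9
  t <- c(0.5, 1, 2, 6)
  one <- conc_one_cpt_transit(t, 300, p0[c("F", "MTT", "NN", "ka", "CL", "V")])
  two <- conc_two_cpt_transit(t, 300, p0)
  expect_equal(two, one, tolerance = 1e-3)
  ## amount eliminated over (0, Inf) equals F * dose
  elim <- integrate(function(tt) conc_two_cpt_transit(tt, 300, p) * p[["CL"]],
                    0, Inf, rel.tol = 1e-8, subdivisions = 400L)$value
  expect_equal(elim, 300, tolerance = 5e-4)
})

test_that("quasi-instantaneous depot approaches transit-direct input", {
  p <- unlist(pyrazinamide_model()$typical)  # ka fixed 50/h
  t <- seq(0.25, 8, by = 0.25)
  with_depot <- conc_one_cpt_transit(t, 1600, p)
  direct <- conc_transit_direct(t, 1600, p[c("F", "MTT", "NN", "CL", "V")])
  expect_equal(with_depot[t > 0.2], direct[t > 0.2], tolerance = 0.01)
})

test_that("steady state by superposition: conservation and short-half-life limit", {
  p <- unlist(pyrazinamide_model()$typical)
  reg <- dose_regimen(1600)
  single <- function(t) conc_one_cpt_transit(t, 1600, p)
  grid <- seq(0, 24, by = 0.05)
  prof <- steady_state_conc(grid, reg, single)
  auc <- sum(diff(grid) * (head(prof, -1) + tail(prof, -1)) / 2)
  ## AUC over one steady-state interval equals F*dose/CL
  expect_equal(auc, 1600 / 4.17, tolerance = 5e-3)
  ## with a very short half-life steady state is indistinguishable from a
  ## single dose (difference below the assay LLOQ)
  fast <- function(t) conc_one_cpt_lag(t, 600, 1, 150, 56.4, 1.21, 0.2)
  ssf <- steady_state_conc(grid, dose_regimen(600), fast)
  expect_lt(max(abs(ssf - fast(grid))), 0.117)
})

test_that("pyrazinamide trough matches the closed-form accumulation oracle", {
  p <- unlist(pyrazinamide_model()$typical)
  reg <- dose_regimen(1600)
  single <- function(t) conc_one_cpt_transit(t, 1600, p)
  ke <- p[["CL"]] / p[["V"]]
  ## by 24 h absorption is complete, so the single-dose tail is a pure
  ## exponential and the steady-state trough is the geometric sum
  trough_ss <- steady_state_conc(24, reg, single)
  trough_1 <- single(24)
  expect_equal(trough_ss, trough_1 / (1 - exp(-24 * ke)), tolerance = 1e-3)
})

test_that("profiles are non-negative everywhere and model_conc dispatches", {
  for (m in list(rifampin_model(), isoniazid_model(), pyrazinamide_model())) {
    p <- unlist(m$typical)
    conc <- model_conc(m, p, 600, c(0, 0.5, 1, 3, 8, 23))
    expect_true(all(conc >= 0))
  }
  ## compiled and R single-dose paths agree for the lag model
  m <- rifampin_model()
  tt <- c(0.5, 1, 2.2, 7.9)
  r_path <- model_conc(m, unlist(m$typical), 600, tt)
  cpp <- tbpk:::.cpp_conc1lag(tt, rep(600, 4), rep(1, 4), rep(25.1, 4),
                              rep(56.4, 4), rep(1.21, 4), rep(0.691, 4),
                              rep(FALSE, 4), 24)
  expect_equal(r_path, cpp, tolerance = 1e-12)
})

test_that("analytic and ODE agreement holds across a parameter grid", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) {
    list(c(-p[["ka"]] * y[1], p[["ka"]] * y[1] - p[["ke"]] * y[2]))
  }
  grid <- expand.grid(CL = 25.1 * c(0.5, 1, 1.5), V = 56.4 * c(0.5, 1.5),
                      ka = 1.21 * c(0.5, 1.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    times <- c(1, 2, 4, 8)
    out <- deSolve::ode(c(600, 0), c(0, times), rhs,
                        c(ka = g$ka, ke = g$CL / g$V),
                        rtol = 1e-10, atol = 1e-12)
    expect_equal(conc_one_cpt_lag(times, 600, 1, g$CL, g$V, g$ka, 0),
                 unname(out[-1, 3] / g$V), tolerance = 1e-3 * 0.1)
  }
})
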