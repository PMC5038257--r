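## Exposure-response: quartiles, rank-sum test, logistic regression.

test_that("quartile assignment follows the tie-to-lower convention", {
  expect_equal(quartile_assign(1:8), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_warning(q <- quartile_assign(rep(5, 10)), "degenerate")
  expect_true(all(q == 1L))
  expect_error(quartile_assign(c(1, 2, 3)), "at least 4")
})

test_that("quartiles hold n/4 +/- 1 observations on continuous data", {
  set.seed(5)
  for (n in c(20, 47, 100)) {
    q <- quartile_assign(rnorm(n))
    expect_true(all(abs(table(q) - n / 4) <= 1))
  }
})

test_that("rank-sum test: identity, separation, exact-enumeration oracle", {
  set.seed(2)
  x <- rnorm(8)
  same <- wilcoxon_rank_sum(x, x)
  expect_gt(same$p_value, 0.9)
  sep <- wilcoxon_rank_sum(rnorm(10), rnorm(10) + 100)
  expect_lt(sep$p_value, 0.001)
  ## brute-force enumeration over all assignments of ranks (n = 4 + 3)
  a <- c(1.2, 3.4, 0.5, 2.2); b <- c(5.0, 0.1, 2.9)
  got <- wilcoxon_rank_sum(a, b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[1:4]) - 4 * 5 / 2
  combs <- combn(7, 4)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - 4 * 5 / 2)
  p_exact <- mean(abs(us - 6) >= abs(u_obs - 6))  # E[U] = n1 n2 / 2 = 6
  expect_equal(got$statistic, u_obs)
  expect_equal(got$p_value, p_exact, tolerance = 1e-10)
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  set.seed(9)
  a <- rlnorm(15); b <- rlnorm(18) * 1.4
  p1 <- wilcoxon_rank_sum(a, b)$p_value
  p2 <- wilcoxon_rank_sum(log(a), log(b))$p_value
  p3 <- wilcoxon_rank_sum(a^3, b^3)$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("logistic fit reproduces the 2x2 cross-product odds ratio", {
  ## exposed: 16 events / 9 non-events; unexposed: 4 / 16
  y <- c(rep(1, 16), rep(0, 9), rep(1, 4), rep(0, 16))
  x <- c(rep(1, 25), rep(0, 20))
  fit <- logistic_fit(y, cbind(exposed = x))
  expect_equal(fit$or[fit$term == "exposed"], (16 * 16) / (9 * 4),
               tolerance = 1e-6)  # 7.111
})

test_that("logistic fit matches glm to 1e-6 on random datasets", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 120
    X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X[, 1] - 0.6 * X[, 2]))
    mine <- logistic_fit(y, X)
    ref <- glm(y ~ X, family = binomial())
    expect_equal(mine$coef, unname(coef(ref)), tolerance = 1e-6)
    ## SEs agree up to the two fitters' convergence tolerances
    expect_equal(mine$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  }
})

test_that("logistic fit flags separation and degenerate inputs", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(rep(0, 10), rep(1, 10))  # perfect separation
  expect_warning(fit <- logistic_fit(y, cbind(x = x)), "separation")
  expect_true(attr(fit, "separation"))
  expect_error(logistic_fit(rep(1, 10), cbind(x = rnorm(10))), "identical")
  expect_error(logistic_fit(y, cbind(a = x, b = x)), "full rank")
})

test_that("large-n null data give odds ratios near 1", {
  set.seed(77)
  y <- rbinom(4000, 1, 0.35)
  x <- rnorm(4000)
  fit <- logistic_fit(y, cbind(x = x))
  expect_lt(abs(fit$or[2] - 1), 0.1)
})

test_that("er_analysis: reference quartile, equivariance, empty adjustment", {
  set.seed(12)
  n <- 400
  expo <- rlnorm(n, log(15), 0.6)
  covs <- data.frame(age = runif(n, 20, 60), prev_inh = rbinom(n, 1, 0.4) == 1,
                     hiv_positive = rbinom(n, 1, 0.65) == 1,
                     alcohol = rbinom(n, 1, 0.37) == 1,
                     diabetes = rbinom(n, 1, 0.04) == 1)
  out <- generate_side_effect_outcomes(expo, seed = 13)
  er <- er_analysis(expo, out$outcome, covs)
  expect_equal(er$quartile_or$or[1], 1)
  expect_equal(er$quartile_or$adj_or[1], 1)
  expect_true(all(er$quartile_or$or > 0))
  ## CI contains the estimate
  with(er$quartile_or[-1, ], {
    expect_true(all(or >= or_lower & or <= or_upper))
  })
  ## empty adjustment set reduces to the unadjusted fit
  er0 <- er_analysis(expo, out$outcome, covs, adjustment = character())
  expect_equal(er0$quartile_or$adj_or, er0$quartile_or$or, tolerance = 1e-10)
  ## relabeling the reference by inverting the exposure flips Q4 vs Q1
  fit_ab <- logistic_fit(out$outcome, cbind(q4 = as.numeric(out$quartile == 4)))
  fit_ba <- logistic_fit(out$outcome, cbind(q4 = as.numeric(out$quartile != 4)))
  expect_equal(fit_ab$or[2], 1 / fit_ba$or[2], tolerance = 1e-8)
})

test_that("unadjusted quartile OR equals the contingency-table cross-product", {
  set.seed(21)
  expo <- rlnorm(200, log(15), 0.6)
  out <- generate_side_effect_outcomes(expo, seed = 22)
  er <- er_analysis(expo, out$outcome, NULL, adjustment = character())
  q <- quartile_assign(expo)
  for (k in 2:4) {
    tab <- table(factor(q == k, c(FALSE, TRUE))[q %in% c(1, k)],
                 factor(out$outcome[q %in% c(1, k)], c(FALSE, TRUE)))
    cp <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
      (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
    expect_equal(er$quartile_or$or[k], unname(cp), tolerance = 1e-6)
  }
})
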