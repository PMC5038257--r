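## Steady-state exposure metrics, low-exposure flags, forward simulation of
## observations under the study design, and visual predictive checks.

#' Steady-state exposure metrics for one parameter set
#'
#' AUC over one 24-h dosing interval at steady state is computed analytically
#' as `F * dose / (CL/F)` and cross-checked by trapezoidal integration of the
#' profile grid (a discrepancy above 0.5% raises a warning). Cmax and Tmax
#' come from a dense grid over the dosing interval (default 0.01-h steps),
#' refined by bounded local maximisation around the best grid point.
#'
#' @param model a [pk_model_spec()].
#' @param params named individual parameter values.
#' @param regimen a [dose_regimen()].
#' @param grid_step profile grid step, h.
#' @param refine refine Cmax by local maximisation?
#' @return one-row data frame: `cmax` (mg/L), `tmax` (h), `auc24` (mg.h/L),
#'   `auc24_trapz`.
#' @export
exposure_metrics <- function(model, params, regimen, grid_step = 0.01,
                             refine = TRUE) {
  params <- unlist(params)
  ii <- regimen$interval
  grid <- seq(0, ii, by = grid_step)
  conc <- ss_profile(model, params, regimen, grid)
  auc <- params[["F"]] * regimen$amount / params[["CL"]]
  auc_tz <- trapz(grid, conc)
  if (abs(auc_tz - auc) / auc > 0.005) {
    warning(sprintf("trapezoidal AUC deviates from F*dose/CL by %.2f%%",
                    100 * abs(auc_tz - auc) / auc))
  }
  i <- which.max(conc)
  cmax <- conc[i]; tmax <- grid[i]
  if (refine) {
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    if (hi > lo) {
      op <- optimize(function(t) ss_profile(model, params, regimen, t),
                     c(lo, hi), maximum = TRUE, tol = 1e-6)
      if (op$objective >= cmax) { cmax <- op$objective; tmax <- op$maximum }
    }
  }
  data.frame(cmax = cmax, tmax = tmax %% ii, auc24 = auc, auc24_trapz = auc_tz)
}

## steady-state profile, using the compiled superposition for the
## one-compartment lag model
ss_profile <- function(model, params, regimen, times) {
  if (model$disposition == "one_compartment" &&
      model$absorption == "first_order_lag") {
    n <- length(times)
    .cpp_conc1lag(times, rep(regimen$amount, n), rep(params[["F"]], n),
                  rep(params[["CL"]], n), rep(params[["V"]], n),
                  rep(params[["ka"]], n), rep(params[["tlag"]], n),
                  rep(TRUE, n), regimen$interval)
  } else {
    model_conc(model, params, regimen, times, steady_state = TRUE)
  }
}

#' Flag low peak exposures
#'
#' Strict-inequality comparison of each subject's Cmax against the drug's
#' recommended threshold (defaults 8, 3, and 35 mg/L for rifampin,
#' isoniazid, and pyrazinamide).
#'
#' @param metrics data frame with columns `drug` and `cmax`.
#' @param thresholds named thresholds, mg/L.
#' @return `metrics` with a logical `low_cmax` column appended.
#' @export
flag_low_exposure <- function(metrics,
                              thresholds = c(rifampin = 8, isoniazid = 3,
                                             pyrazinamide = 35)) {
  unknown <- setdiff(unique(metrics$drug), names(thresholds))
  if (length(unknown)) stop("no threshold for drug(s): ",
                            paste(unknown, collapse = ", "))
  metrics$low_cmax <- metrics$cmax < unname(thresholds[metrics$drug])
  metrics
}

## draw one set of random effects for a cohort: list with eta matrix
## (n x d_iiv) and kappa array entries per occasion
draw_random_effects <- function(model, n) {
  layout <- ranef_layout(model)
  d <- nrow(layout)
  if (d == 0) return(matrix(0, n, 0))
  om <- vapply(seq_len(d), function(j) {
    p <- layout$param[j]
    if (layout$occasion[j] == "both") model$iiv[[p]] else model$iov[[p]]
  }, numeric(1))
  E <- matrix(rnorm(n * d, 0, rep(sqrt(om), each = n)), n, d)
  colnames(E) <- layout$eta
  E
}

#' Simulate observations under the study design
#'
#' Draws interindividual and interoccasion random effects and residual
#' errors, evaluates each subject's profile at the design's sampling times
#' (the predose sample on the steady-state profile, post-dose samples on the
#' observed-dose profile), and applies LLOQ censoring: simulated
#' concentrations below the LLOQ are flagged BLQ with the concentration
#' suppressed.
#'
#' @param model a [pk_model_spec()].
#' @param cohort a [generate_cohort()] data frame (ignored when `design`
#'   is supplied with covariate columns).
#' @param seed RNG seed.
#' @param design optional pre-built design event table (rows are refilled);
#'   built with [build_design()] from the cohort otherwise.
#' @param ii dosing interval, h.
#' @return a simulated event table.
#' @export
simulate_observations <- function(model, cohort = NULL, seed = NULL,
                                  design = NULL, ii = 24) {
  if (is.null(design)) {
    if (is.null(cohort)) stop("need a cohort or a design")
    design <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
      build_design(cohort[i, ], model$drug)
    }))
  }
  design <- as.data.frame(design)
  ids <- unique(design$id)
  layout <- ranef_layout(model)
  with_seed(seed, {
    E <- draw_random_effects(model, length(ids))
    rownames(E) <- ids
    mix_mult <- rep(1, length(ids))
    if (!is.null(model$mixture)) {
      comp <- sample.int(length(model$mixture$proportions), length(ids),
                         replace = TRUE, prob = model$mixture$proportions)
      mix_mult <- model$mixture$multipliers[comp]
    }
    names(mix_mult) <- ids
    out <- design
    obs_idx <- which(out$evid == 0)
    fast <- model$disposition == "one_compartment" &&
      model$absorption == "first_order_lag"
    if (fast) {
      rows <- out[obs_idx, ]
      P <- matrix(NA_real_, length(obs_idx), 5,
                  dimnames = list(NULL, c("F", "CL", "V", "ka", "tlag")))
      dose_v <- numeric(length(obs_idx))
      for (sid in ids) {
        sel <- which(rows$id == sid)
        subj <- as_subject(as.list(rows[sel[1], , drop = FALSE]))
        typ <- individual_typical_params(model, subj)
        typ["CL"] <- typ["CL"] * mix_mult[sid]
        dose_v[sel] <- out$amt[out$id == sid & out$evid == 1][1]
        for (occ in c("predose", "intensive")) {
          ssel <- sel[rows$occasion[sel] == occ]
          if (!length(ssel)) next
          lp <- log(typ[c("F", "CL", "V", "ka", "tlag")])
          use <- layout$occasion == "both" | layout$occasion == occ
          for (j in which(use)) lp[layout$param[j]] <- lp[layout$param[j]] + E[sid, j]
          P[ssel, ] <- matrix(exp(lp), length(ssel), 5, byrow = TRUE)
        }
      }
      is_pre <- rows$occasion == "predose"
      tt <- ifelse(is_pre, ii, rows$time)
      pred <- .cpp_conc1lag(tt, dose_v, P[, "F"], P[, "CL"], P[, "V"],
                            P[, "ka"], P[, "tlag"], is_pre, ii)
    } else {
      pred <- numeric(length(obs_idx))
      rows <- out[obs_idx, ]
      for (sid in ids) {
        sel <- which(rows$id == sid)
        subj <- as_subject(as.list(rows[sel[1], , drop = FALSE]))
        typ <- individual_typical_params(model, subj)
        typ[model$mixture$param %||% "CL"] <-
          typ[model$mixture$param %||% "CL"] *
          (if (is.null(model$mixture)) 1 else mix_mult[sid])
        dose <- out$amt[out$id == sid & out$evid == 1][1]
        regimen <- dose_regimen(dose, ii)
        for (occ in c("predose", "intensive")) {
          ssel <- sel[rows$occasion[sel] == occ]
          if (!length(ssel)) next
          lp <- log(typ)
          use <- layout$occasion == "both" | layout$occasion == occ
          for (j in which(use)) lp[layout$param[j]] <- lp[layout$param[j]] + E[sid, j]
          p_i <- exp(lp)
          pred[ssel] <- if (occ == "predose") {
            model_conc(model, p_i, regimen, rep(ii, length(ssel)),
                       steady_state = TRUE)
          } else {
            model_conc(model, p_i, dose, rows$time[ssel])
          }
        }
      }
    }
    y <- pred + rnorm(length(pred), 0,
                      residual_sd(pred, model$error$a, model$error$b))
    lloq <- out$lloq[obs_idx]
    blq <- y < lloq
    out$dv[obs_idx] <- ifelse(blq, NA_real_, y)
    out$blq[obs_idx] <- blq
    validate_event_table(out)
  })
}

#' Per-subject steady-state exposures for a cohort
#'
#' Draws each subject's individual parameters (intensive-occasion random
#' effects applied to the covariate-adjusted typical values) and derives the
#' steady-state exposure metrics.
#'
#' @param model a [pk_model_spec()].
#' @param cohort a [generate_cohort()] data frame.
#' @param seed RNG seed.
#' @param grid_step profile grid step, h.
#' @return data frame of class `tbpk_exposure`: one row per subject with
#'   `id`, `drug`, `dose`, `cmax`, `tmax`, `auc24`.
#' @export
simulate_exposures <- function(model, cohort, seed = NULL, grid_step = 0.01) {
  layout <- ranef_layout(model)
  with_seed(seed, {
    E <- draw_random_effects(model, nrow(cohort))
    out <- lapply(seq_len(nrow(cohort)), function(i) {
      subj <- cohort[i, ]
      typ <- individual_typical_params(model, subj)
      lp <- log(typ)
      use <- layout$occasion %in% c("both", "intensive")
      for (j in which(use)) lp[layout$param[j]] <- lp[layout$param[j]] + E[i, j]
      dose <- assign_who_band_dose(subj$weight)$mg[[model$drug]]
      m <- exposure_metrics(model, exp(lp), dose_regimen(dose),
                            grid_step = grid_step)
      cbind(data.frame(id = subj$id, drug = model$drug, dose = dose,
                       stringsAsFactors = FALSE), m)
    })
    out <- do.call(rbind, out)
    class(out) <- c("tbpk_exposure", "data.frame")
    out
  })
}

#' Visual predictive check
#'
#' Per nominal-time bin (the design's sampling times, with the predose sample
#' as its own bin), the observed 10/50/90th percentiles are compared with
#' simulation-based confidence bands: the model simulates `nsim` replicates
#' of the dataset under its own design, and the band for each percentile is
#' the central `ci`% interval of that percentile across replicates. BLQ
#' observations (observed and simulated) enter the percentile computation at
#' LLOQ/2, and the observed versus simulated BLQ fraction per bin is
#' reported alongside. Optional stratification (e.g. by HIV/LPV-r status).
#'
#' @param model a [pk_model_spec()] (typically a fit's `final_model`).
#' @param data observed event table.
#' @param nsim number of simulated replicates (default 500).
#' @param percentiles percentiles to display.
#' @param ci confidence-band level, percent.
#' @param strata `NULL`, a covariate column name, or a function of a subject
#'   row returning a stratum label.
#' @param seed RNG seed.
#' @param ii dosing interval, h.
#' @return list of class `tbpk_vpc`: `bins` (stratum, occasion, time,
#'   percentile, observed, lo, hi), `blq` (per-bin BLQ fractions), `nsim`.
#' @export
vpc <- function(model, data, nsim = 500L, percentiles = c(10, 50, 90),
                ci = 90, strata = NULL, seed = 1L, ii = 24) {
  data <- as.data.frame(data)
  obs <- data[data$evid == 0 & (data$blq | !is.na(data$dv)), , drop = FALSE]
  stratum_of <- function(rows) {
    if (is.null(strata)) rep("all", nrow(rows))
    else if (is.character(strata) && length(strata) == 1) as.character(rows[[strata]])
    else vapply(seq_len(nrow(rows)), function(i) as.character(strata(rows[i, ])), "")
  }
  obs$stratum <- stratum_of(obs)
  empty <- setdiff(unique(stratum_of(data[data$evid == 0, , drop = FALSE])),
                   unique(obs$stratum))
  if (length(empty)) warning("empty stratum(s) omitted: ",
                             paste(empty, collapse = ", "))
  obs$bin <- paste(obs$stratum, obs$occasion, obs$time, sep = "|")
  val <- function(d) ifelse(d$blq, d$lloq / 2, d$dv)
  bins <- unique(obs[, c("stratum", "occasion", "time", "bin")])
  bins <- bins[order(bins$stratum, bins$occasion != "predose", bins$time), ]
  pct_by_bin <- function(d) {
    v <- val(d)
    t(vapply(bins$bin, function(b) {
      x <- v[d$bin == b]
      if (!length(x)) rep(NA_real_, length(percentiles))
      else quantile(x, percentiles / 100, names = FALSE, type = 7)
    }, numeric(length(percentiles))))
  }
  blq_by_bin <- function(d) {
    vapply(bins$bin, function(b) mean(d$blq[d$bin == b]), numeric(1))
  }
  obs_pct <- pct_by_bin(obs)
  obs_blq <- blq_by_bin(obs)
  sim_pct <- array(NA_real_, c(nrow(bins), length(percentiles), nsim))
  sim_blq <- matrix(NA_real_, nrow(bins), nsim)
  for (s in seq_len(nsim)) {
    sim <- simulate_observations(model, design = data,
                                 seed = if (is.null(seed)) NULL else seed + s,
                                 ii = ii)
    simo <- sim[sim$evid == 0, , drop = FALSE]
    simo <- simo[simo$blq | !is.na(simo$dv), , drop = FALSE]
    simo$stratum <- stratum_of(simo)
    simo$bin <- paste(simo$stratum, simo$occasion, simo$time, sep = "|")
    sim_pct[, , s] <- pct_by_bin(simo)
    sim_blq[, s] <- blq_by_bin(simo)
  }
  alpha <- (1 - ci / 100) / 2
  res <- do.call(rbind, lapply(seq_along(percentiles), function(k) {
    lo <- apply(sim_pct[, k, , drop = FALSE], 1, quantile, probs = alpha,
                na.rm = TRUE)
    hi <- apply(sim_pct[, k, , drop = FALSE], 1, quantile, probs = 1 - alpha,
                na.rm = TRUE)
    data.frame(stratum = bins$stratum, occasion = bins$occasion,
               time = bins$time, percentile = percentiles[k],
               observed = obs_pct[, k], lo = lo, hi = hi,
               stringsAsFactors = FALSE)
  }))
  blq_df <- data.frame(
    stratum = bins$stratum, occasion = bins$occasion, time = bins$time,
    observed = obs_blq,
    simulated = apply(sim_blq, 1, median, na.rm = TRUE),
    lo = apply(sim_blq, 1, quantile, probs = alpha, na.rm = TRUE),
    hi = apply(sim_blq, 1, quantile, probs = 1 - alpha, na.rm = TRUE),
    stringsAsFactors = FALSE)
  structure(list(bins = res, blq = blq_df, nsim = nsim, ci = ci,
                 percentiles = percentiles),
            class = "tbpk_vpc")
}

#' @export
print.tbpk_vpc <- function(x, ...) {
  cat(sprintf("<tbpk_vpc> %d simulations, %g%% bands\n", x$nsim, x$ci))
  inside <- with(x$bins, observed >= lo & observed <= hi)
  cat(sprintf("observed percentiles inside bands: %d/%d (%.0f%%)\n",
              sum(inside, na.rm = TRUE), sum(!is.na(inside)),
              100 * mean(inside, na.rm = TRUE)))
  invisible(x)
}

#' Plot a visual predictive check
#'
#' @param x a `tbpk_vpc`.
#' @param ... unused.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot.tbpk_vpc <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for VPC plots")
  }
  b <- x$bins
  b$percentile <- factor(b$percentile)
  ggplot2::ggplot(b, ggplot2::aes(x = time, group = percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = observed, linetype = percentile)) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "time after dose (h)", y = "concentration (mg/L)")
}
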