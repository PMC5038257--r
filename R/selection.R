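## Stepwise covariate selection driven by likelihood-ratio OFV differences:
## forward inclusion at dOFV > 3.84 (alpha = 0.05, 1 df), backward
## elimination at dOFV > 6.63 (alpha = 0.01, 1 df).

#' Likelihood-ratio test OFV cutoff
#'
#' Chi-square quantile at `1 - alpha` with `df` degrees of freedom; the OFV
#' difference between nested models is compared against it.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return OFV cutoff.
#' @examples
#' lrt_threshold(0.05, 1)  # 3.84
#' lrt_threshold(0.01, 1)  # 6.63
#' @export
lrt_threshold <- function(alpha, df = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  qchisq(1 - alpha, df)
}

#' Stepwise forward-inclusion / backward-elimination covariate search
#'
#' Forward: repeatedly fit each remaining candidate effect on top of the
#' current model and add the one with the largest OFV drop, as long as that
#' drop exceeds `forward_cutoff`. Backward: repeatedly remove the retained
#' effect whose removal increases the OFV least, as long as that increase
#' does not exceed `backward_cutoff`. All fits share the same estimation
#' settings, so nested comparisons are free of Monte-Carlo noise; ties in
#' dOFV break lexicographically by declared candidate order. A candidate
#' whose fit does not converge is skipped with a warning and recorded in the
#' trace.
#'
#' @param data event table.
#' @param base_model starting [pk_model_spec()].
#' @param candidates list of [covariate_effect()] candidates.
#' @param forward_cutoff OFV drop required for inclusion (default 3.84,
#'   alpha = 0.05 with 1 df).
#' @param backward_cutoff OFV increase beyond which removal is rejected
#'   (default 6.63, alpha = 0.01 with 1 df).
#' @param settings shared [fit_settings()].
#' @param theta_starts multiplier starting values tried for each candidate
#'   fit (the best-likelihood result is kept), guarding against a fit
#'   settling on a local ridge near the null value.
#' @return list of class `tbpk_selection`: `final_model`, `final_fit`,
#'   `trace` (data frame of steps), `base_ofv`.
#' @export
stepwise_select <- function(data, base_model, candidates,
                            forward_cutoff = 3.84, backward_cutoff = 6.63,
                            settings = fit_settings(),
                            theta_starts = c(1, 0.75, 4 / 3)) {
  labels <- vapply(candidates, function(e) e$label, "")
  if (anyDuplicated(labels)) stop("candidate labels must be unique")
  trace <- list()
  note <- function(phase, label, dofv, decision) {
    trace[[length(trace) + 1]] <<- data.frame(
      step = length(trace) + 1L, phase = phase, candidate = label,
      delta_ofv = dofv, decision = decision, stringsAsFactors = FALSE)
  }
  ## every fit starts cold from the declared model values with identical
  ## settings: a nested fit warm-started at the other model's optimum tends
  ## to sit down on a flat ridge of the new parameter and stall there
  fit_quiet <- function(model) {
    f <- tryCatch(fit_model(data, model, settings), error = function(e) NULL)
    if (!is.null(f) && !f$convergence$converged) f$failed <- TRUE
    f
  }
  current <- base_model
  current_fit <- fit_quiet(current)
  if (is.null(current_fit)) stop("base model fit failed")
  base_ofv <- current_fit$ofv
  remaining <- seq_along(candidates)
  retained <- integer()
  ## forward inclusion
  repeat {
    if (!length(remaining)) break
    dofvs <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      idx <- remaining[k]
      f <- NULL
      for (th0 in theta_starts) {
        eff <- candidates[[idx]]
        if (eff$kind == "categorical") eff$theta <- eff$theta * th0
        fk <- fit_quiet(set_covariates(current, add = eff))
        if (!is.null(fk) && !isTRUE(fk$failed) &&
            (is.null(f) || fk$ofv < f$ofv)) f <- fk
      }
      if (is.null(f) || isTRUE(f$failed)) {
        warning("candidate '", labels[idx], "' did not converge; skipped")
        note("forward", labels[idx], NA_real_, "skipped (non-convergent)")
        next
      }
      dofvs[k] <- current_fit$ofv - f$ofv
      fits[[k]] <- f
      note("forward", labels[idx], dofvs[k], "evaluated")
    }
    if (all(is.na(dofvs)) || max(dofvs, na.rm = TRUE) <= forward_cutoff) break
    best <- which(dofvs == max(dofvs, na.rm = TRUE))[1]  # lexicographic tie-break
    idx <- remaining[best]
    note("forward", labels[idx], dofvs[best], "included")
    current <- set_covariates(current, add = candidates[[idx]])
    current_fit <- fits[[best]]
    retained <- c(retained, idx)
    remaining <- setdiff(remaining, idx)
  }
  ## backward elimination
  repeat {
    if (!length(retained)) break
    incr <- rep(NA_real_, length(retained))
    fits <- vector("list", length(retained))
    for (k in seq_along(retained)) {
      idx <- retained[k]
      f <- fit_quiet(set_covariates(current, drop = labels[idx]))
      if (is.null(f) || isTRUE(f$failed)) {
        note("backward", labels[idx], NA_real_, "skipped (non-convergent)")
        next
      }
      incr[k] <- f$ofv - current_fit$ofv
      fits[[k]] <- f
      note("backward", labels[idx], incr[k], "evaluated")
    }
    if (all(is.na(incr)) || min(incr, na.rm = TRUE) > backward_cutoff) break
    worst <- which(incr == min(incr, na.rm = TRUE))[1]
    idx <- retained[worst]
    note("backward", labels[idx], incr[worst], "removed")
    current <- set_covariates(current, drop = labels[idx])
    current_fit <- fits[[worst]]
    retained <- setdiff(retained, idx)
  }
  structure(list(final_model = current, final_fit = current_fit,
                 retained = labels[retained],
                 trace = do.call(rbind, trace) %||%
                   data.frame(step = integer(), phase = character(),
                              candidate = character(), delta_ofv = numeric(),
                              decision = character()),
                 base_ofv = base_ofv),
            class = "tbpk_selection")
}

#' Replay a selection trace
#'
#' Re-applies the include/remove decisions recorded in a selection trace to
#' the base model; with the same data and settings this reproduces the final
#' model exactly.
#'
#' @param base_model the base [pk_model_spec()].
#' @param candidates the candidate list given to [stepwise_select()].
#' @param trace the `trace` data frame of a `tbpk_selection`.
#' @return the reconstructed final model.
#' @export
replay_trace <- function(base_model, candidates, trace) {
  labels <- vapply(candidates, function(e) e$label, "")
  current <- base_model
  for (r in seq_len(nrow(trace))) {
    lbl <- trace$candidate[r]
    if (trace$decision[r] == "included") {
      current <- set_covariates(current, add = candidates[[match(lbl, labels)]])
    } else if (trace$decision[r] == "removed") {
      current <- set_covariates(current, drop = lbl)
    }
  }
  current
}

#' Compare alternative covariate codings on one parameter
#'
#' Fits each mutually exclusive coding on top of the base model and ranks
#' them by OFV drop (e.g. HIV serostatus versus ART status as the predictor
#' of clearance).
#'
#' @param data event table.
#' @param base_model base [pk_model_spec()].
#' @param codings list of alternative [covariate_effect()]s (may be empty).
#' @param settings shared [fit_settings()].
#' @return data frame with `coding`, `delta_ofv`, `rank` (1 = best),
#'   `converged`, ordered by rank.
#' @export
compare_covariate_codings <- function(data, base_model, codings,
                                      settings = fit_settings()) {
  if (!length(codings)) {
    return(data.frame(coding = character(), delta_ofv = numeric(),
                      rank = integer(), converged = logical()))
  }
  base_fit <- fit_model(data, base_model, settings)
  res <- lapply(codings, function(eff) {
    f <- tryCatch(fit_model(data, set_covariates(base_model, add = eff),
                            settings),
                  error = function(e) NULL)
    if (is.null(f)) {
      data.frame(coding = eff$label, delta_ofv = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(coding = eff$label, delta_ofv = base_fit$ofv - f$ofv,
                 converged = f$convergence$converged, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$delta_ofv, seq_len(nrow(out))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("coding", "delta_ofv", "rank", "converged")]
}
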