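## Exposure-response analysis of 2-month side effects: exposure quartiles,
## rank-sum comparisons, and logistic-regression odds ratios (unadjusted and
## confounder-adjusted).

#' Assign exposure quartiles
#'
#' Sample quartile cutpoints (inclusive empirical-quantile convention, R type
#' 7); values tied with a cutpoint go to the lower quartile. Quartile 1 is
#' the reference. If all cutpoints coincide (degenerate data) every value is
#' assigned quartile 1 with a warning.
#'
#' @param values numeric exposure metric, length >= 4.
#' @return integer quartile labels 1-4.
#' @export
quartile_assign <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (length(unique(q)) == 1 && all(values == q[1])) {
    warning("degenerate quartile cutpoints; all values assigned quartile 1")
    return(rep(1L, length(values)))
  }
  1L + (values > q[1]) + (values > q[2]) + (values > q[3])
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two groups: exact enumeration when the combined
#' sample size is at most 20 (and no ties), the tie-corrected normal
#' approximation otherwise.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return list with `statistic` (Mann-Whitney U for group_a) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  exact <- (length(group_a) + length(group_b)) <= 20
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact,
                                     correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression; odds ratios are `exp(coef)` with
#' Wald 95% confidence intervals `exp(coef +/- 1.96 SE)`. Separation (a
#' diverging coefficient) is detected and flagged - no silent estimate is
#' returned.
#'
#' @param outcomes binary outcome vector (logical or 0/1).
#' @param design numeric covariate matrix (no intercept column; one is
#'   added), or a data frame coerced to one.
#' @return data frame with `term`, `coef`, `se`, `or`, `or_lower`,
#'   `or_upper`; attribute `separation` (logical), `converged` (logical).
#' @export
logistic_fit <- function(outcomes, design) {
  y <- as.numeric(outcomes)
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary")
  if (all(y == y[1])) stop("outcomes must not all be identical")
  X <- as.matrix(cbind("(Intercept)" = 1, design))
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in 1:100) {
    lp <- drop(X %*% beta)
    mu <- plogis(lp)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, crossprod(X, y - mu)),
                     error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) { converged <- TRUE; break }
  }
  separation <- !converged || max(abs(beta)) > 15
  mu <- plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  cov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, ncol(X)) else sqrt(diag(cov))
  out <- data.frame(term = colnames(X), coef = beta, se = se,
                    or = exp(beta), or_lower = exp(beta - 1.96 * se),
                    or_upper = exp(beta + 1.96 * se),
                    stringsAsFactors = FALSE)
  attr(out, "separation") <- separation
  attr(out, "converged") <- converged
  if (separation) warning("possible separation: coefficient diverging")
  out
}

#' Exposure-response analysis of reported side effects
#'
#' Quartiles of an exposure metric (reference: quartile 1) are entered as
#' indicator variables in a logistic model for the binary side-effect
#' outcome, unadjusted and adjusted for confounders (default set: age per
#' 10-year increase, previous isoniazid treatment, HIV-1 serostatus, alcohol
#' intake, type-2 diabetes). Group medians/IQRs and the rank-sum comparison
#' of exposures between outcome groups are reported alongside.
#'
#' @param exposures per-subject exposure metric (e.g. isoniazid AUC0-24).
#' @param outcomes binary side-effect indicator.
#' @param covariates data frame of adjustment covariates (columns `age`,
#'   `prev_inh`, `hiv_positive`, `alcohol`, `diabetes`), or `NULL` /
#'   zero-column for the unadjusted-only analysis.
#' @param adjustment character vector naming the covariate columns to adjust
#'   for (empty = adjusted model identical to unadjusted).
#' @return list of class `tbpk_er`: `quartile_or` (per-quartile unadjusted
#'   and adjusted ORs with 95% CIs), `covariate_or`, `rank_sum`,
#'   `group_summary`.
#' @export
er_analysis <- function(exposures, outcomes, covariates = NULL,
                        adjustment = c("age", "prev_inh", "hiv_positive",
                                       "alcohol", "diabetes")) {
  n <- length(exposures)
  if (length(outcomes) != n) stop("exposures and outcomes length mismatch")
  q <- quartile_assign(exposures)
  Q <- sapply(2:4, function(k) as.numeric(q == k))
  colnames(Q) <- paste0("Q", 2:4)
  unadj <- logistic_fit(outcomes, Q)
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(n))
  adjustment <- intersect(adjustment, names(covariates))
  A <- Q
  if (length(adjustment)) {
    Z <- covariates[, adjustment, drop = FALSE]
    if ("age" %in% adjustment) Z$age <- Z$age / 10  # per 10-year increase
    Z <- as.matrix(data.frame(lapply(Z, as.numeric)))
    A <- cbind(Q, Z)
  }
  adj <- logistic_fit(outcomes, A)
  pick <- function(fit, terms) fit[match(terms, fit$term), , drop = FALSE]
  qtab <- data.frame(
    quartile = 1:4,
    or = c(1, pick(unadj, paste0("Q", 2:4))$or),
    or_lower = c(NA, pick(unadj, paste0("Q", 2:4))$or_lower),
    or_upper = c(NA, pick(unadj, paste0("Q", 2:4))$or_upper),
    adj_or = c(1, pick(adj, paste0("Q", 2:4))$or),
    adj_or_lower = c(NA, pick(adj, paste0("Q", 2:4))$or_lower),
    adj_or_upper = c(NA, pick(adj, paste0("Q", 2:4))$or_upper))
  grp <- function(v) sprintf("%.3g (%.3g-%.3g)", median(v),
                             quantile(v, 0.25), quantile(v, 0.75))
  yes <- as.logical(outcomes)
  rs <- wilcoxon_rank_sum(exposures[yes], exposures[!yes])
  structure(list(
    quartile_or = qtab,
    covariate_or = if (length(adjustment)) {
      adj[adj$term %in% colnames(A)[-(1:3)], , drop = FALSE]
    } else adj[0, ],
    rank_sum = rs,
    group_summary = data.frame(group = c("side effects", "no side effects"),
                               n = c(sum(yes), sum(!yes)),
                               median_iqr = c(grp(exposures[yes]),
                                              grp(exposures[!yes])),
                               stringsAsFactors = FALSE)),
    class = "tbpk_er")
}

#' @export
print.tbpk_er <- function(x, ...) {
  cat("<tbpk_er> exposure-response analysis\n")
  print(x$quartile_or, row.names = FALSE, digits = 3)
  cat(sprintf("rank-sum p = %.4g\n", x$rank_sum$p_value))
  invisible(x)
}
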