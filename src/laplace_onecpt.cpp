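// Fast inner Laplace step for the one-compartment, first-order-absorption
// with-lag-time structural model (the rifampin model family). Parameter
// order is fixed as (F, CL, V, ka, tlag). Random effects enter lognormally,
// mapped by (parameter index, occasion code): occasion 0 = both occasions
// (interindividual), 1 = predose only, 2 = intensive only (interoccasion).
// The predose observation is evaluated on the steady-state profile at the
// end of the prior dosing interval; post-dose observations on the
// observed-dose profile. BLQ observations contribute the left-censored (M3)
// probability.
//
// The absorption lag time makes the conditional density only piecewise
// smooth in a lag random effect (the predicted concentration at a sampling
// time has a cliff where the individual lag crosses it), which defeats
// curvature-based (Laplace) marginalisation of that dimension. The
// intensive-occasion lag effect is therefore integrated *inside* the
// conditional likelihood as a finite quadrature mixture (node values and
// log-weights supplied by the caller, Gauss-Hermite against the lognormal
// prior); the remaining dimensions stay smooth and are integrated by
// Laplace.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double conc1lag(double t, double dose, double F, double CL, double V,
                       double ka, double tlag) {
  double ke = CL / V;
  double tau = t - tlag;
  if (tau <= 0.0) return 0.0;
  if (std::fabs(ka - ke) / ke < 1e-6)
    return F * dose * ka * tau * std::exp(-ka * tau) / V;
  return F * dose * ka / (V * (ka - ke)) *
         (std::exp(-ke * tau) - std::exp(-ka * tau));
}

static double conc1lag_ss(double tii, double ii, double dose, double F,
                          double CL, double V, double ka, double tlag) {
  double total = conc1lag(tii, dose, F, CL, V, ka, tlag);
  for (int k = 1; k <= 1000; ++k) {
    double term = conc1lag(tii + k * ii, dose, F, CL, V, ka, tlag);
    total += term;
    if (k >= 2 && term <= 1e-8 * std::max(total, 1e-300)) break;
  }
  return total;
}

static inline double obs_nll_1(double dvi, bool blqi, double lloqi,
                               double pred, double a, double b) {
  double sd = std::sqrt(a * a + b * b * pred * pred);
  if (blqi) return -R::pnorm(lloqi, pred, sd, 1, 1);
  return -R::dnorm(dvi, pred, sd, 1);
}

// joint -log density: data nll (with optional lag-mixture marginalisation of
// the intensive-occasion lag effect) plus the Gaussian prior of eta
static double joint_nll(const arma::vec& eta, const NumericVector& t,
                        const NumericVector& dv, const LogicalVector& blq,
                        const NumericVector& lloq, const IntegerVector& occ,
                        double dose, double ii, const arma::vec& logtyp,
                        const IntegerMatrix& map, const arma::vec& omega2,
                        double a, double b, const arma::vec& mix_kappa,
                        const arma::vec& mix_logw, const arma::vec& mix2_kappa,
                        const arma::vec& mix2_logw) {
  arma::vec lp1 = logtyp, lp2 = logtyp;  // occasion 1 = predose, 2 = intensive
  for (arma::uword j = 0; j < eta.n_elem; ++j) {
    int p = map(j, 0), oc = map(j, 1);
    if (oc == 0) { lp1(p) += eta(j); lp2(p) += eta(j); }
    else if (oc == 1) lp1(p) += eta(j);
    else lp2(p) += eta(j);
  }
  arma::vec p1 = arma::exp(lp1), p2 = arma::exp(lp2);
  double nll = 0.0;
  // predose observations do not depend on the intensive-occasion lag
  double pred_ss = -1.0;
  for (int i = 0; i < t.size(); ++i) {
    if (occ[i] == 1) {
      if (pred_ss < 0.0)
        pred_ss = conc1lag_ss(ii, ii, dose, p1(0), p1(1), p1(2), p1(3), p1(4));
      nll += obs_nll_1(dv[i], blq[i], lloq[i], pred_ss, a, b);
    }
  }
  arma::uword K1 = mix_kappa.n_elem, K2 = mix2_kappa.n_elem;
  if (K1 == 0 && K2 == 0) {
    for (int i = 0; i < t.size(); ++i) {
      if (occ[i] != 1) {
        double pred = conc1lag(t[i], dose, p2(0), p2(1), p2(2), p2(3), p2(4));
        nll += obs_nll_1(dv[i], blq[i], lloq[i], pred, a, b);
      }
    }
  } else {
    // subject-level quadrature mixture over the intensive-occasion lag
    // and/or absorption-rate effects: log sum_{k,l} w_k w_l L(tlag_k, ka_l)
    arma::uword n1 = std::max(K1, (arma::uword)1);
    arma::uword n2 = std::max(K2, (arma::uword)1);
    arma::vec lcomp(n1 * n2);
    arma::uword c = 0;
    for (arma::uword k = 0; k < n1; ++k) {
      double tlag_k = (K1 > 0) ? std::exp(lp2(4) + mix_kappa(k))
                               : std::exp(lp2(4));
      double lw_k = (K1 > 0) ? mix_logw(k) : 0.0;
      for (arma::uword l = 0; l < n2; ++l) {
        double ka_l = (K2 > 0) ? std::exp(lp2(3) + mix2_kappa(l))
                               : std::exp(lp2(3));
        double lw = lw_k + ((K2 > 0) ? mix2_logw(l) : 0.0);
        double ll = 0.0;
        for (int i = 0; i < t.size(); ++i) {
          if (occ[i] != 1) {
            double pred = conc1lag(t[i], dose, p2(0), p2(1), p2(2), ka_l, tlag_k);
            ll -= obs_nll_1(dv[i], blq[i], lloq[i], pred, a, b);
          }
        }
        lcomp(c++) = lw + ll;
      }
    }
    double mx = lcomp.max();
    nll -= mx + std::log(arma::accu(arma::exp(lcomp - mx)));
  }
  for (arma::uword j = 0; j < eta.n_elem; ++j)
    nll += 0.5 * (eta(j) * eta(j) / omega2(j) +
                  std::log(2.0 * M_PI * omega2(j)));
  return nll;
}

// [[Rcpp::export(name = ".cpp_onecpt_joint_nll")]]
double cpp_onecpt_joint_nll(const arma::vec& eta, const NumericVector& t,
                            const NumericVector& dv, const LogicalVector& blq,
                            const NumericVector& lloq, const IntegerVector& occ,
                            double dose, double ii, const arma::vec& logtyp,
                            const IntegerMatrix& map, const arma::vec& omega2,
                            double a, double b,
                            const arma::vec& mix_kappa,
                            const arma::vec& mix_logw,
                            const arma::vec& mix2_kappa,
                            const arma::vec& mix2_logw) {
  return joint_nll(eta, t, dv, blq, lloq, occ, dose, ii, logtyp, map, omega2,
                   a, b, mix_kappa, mix_logw, mix2_kappa, mix2_logw);
}

#define NLL(e) joint_nll((e), t, dv, blq, lloq, occ, dose, ii, logtyp, map, \
                         omega2, a, b, mix_kappa, mix_logw, mix2_kappa, \
                         mix2_logw)

static arma::vec fd_grad(const arma::vec& eta, double h, const NumericVector& t,
                         const NumericVector& dv, const LogicalVector& blq,
                         const NumericVector& lloq, const IntegerVector& occ,
                         double dose, double ii, const arma::vec& logtyp,
                         const IntegerMatrix& map, const arma::vec& omega2,
                         double a, double b, const arma::vec& mix_kappa,
                         const arma::vec& mix_logw, const arma::vec& mix2_kappa,
                         const arma::vec& mix2_logw) {
  arma::uword d = eta.n_elem;
  arma::vec g(d);
  for (arma::uword j = 0; j < d; ++j) {
    double hj = h * std::max(1.0, std::fabs(eta(j)));
    arma::vec ep = eta, em = eta;
    ep(j) += hj; em(j) -= hj;
    g(j) = (NLL(ep) - NLL(em)) / (2.0 * hj);
  }
  return g;
}

static arma::mat fd_hess(const arma::vec& eta, double h, const NumericVector& t,
                         const NumericVector& dv, const LogicalVector& blq,
                         const NumericVector& lloq, const IntegerVector& occ,
                         double dose, double ii, const arma::vec& logtyp,
                         const IntegerMatrix& map, const arma::vec& omega2,
                         double a, double b, const arma::vec& mix_kappa,
                         const arma::vec& mix_logw, const arma::vec& mix2_kappa,
                         const arma::vec& mix2_logw) {
  arma::uword d = eta.n_elem;
  arma::mat H(d, d);
  for (arma::uword i = 0; i < d; ++i) {
    double hi = h * std::max(1.0, std::fabs(eta(i)));
    for (arma::uword j = 0; j <= i; ++j) {
      double hj = h * std::max(1.0, std::fabs(eta(j)));
      arma::vec epp = eta, epm = eta, emp = eta, emm = eta;
      epp(i) += hi; epp(j) += hj;
      epm(i) += hi; epm(j) -= hj;
      emp(i) -= hi; emp(j) += hj;
      emm(i) -= hi; emm(j) -= hj;
      H(i, j) = H(j, i) = (NLL(epp) - NLL(epm) - NLL(emp) + NLL(emm)) /
                          (4.0 * hi * hj);
    }
  }
  return H;
}

// Dampened Newton minimisation of the joint nll from each start column;
// returns the Laplace-approximate marginal -log-likelihood, the mode, the
// Hessian at the mode, and a convergence flag.
// [[Rcpp::export(name = ".cpp_onecpt_laplace")]]
List cpp_onecpt_laplace(const arma::mat& eta_starts, const NumericVector& t,
                        const NumericVector& dv, const LogicalVector& blq,
                        const NumericVector& lloq, const IntegerVector& occ,
                        double dose, double ii, const arma::vec& logtyp,
                        const IntegerMatrix& map, const arma::vec& omega2,
                        double a, double b, const arma::vec& mix_kappa,
                        const arma::vec& mix_logw, const arma::vec& mix2_kappa,
                        const arma::vec& mix2_logw, double tol = 1e-6,
                        int max_iter = 100) {
  arma::uword d = eta_starts.n_rows;
  if (d == 0) {
    arma::vec e0;
    double f0 = NLL(e0);
    return List::create(_["nll"] = f0, _["eta"] = NumericVector(0),
                        _["hess"] = NumericMatrix(0, 0), _["conv"] = true);
  }
  const double fdh = 1e-4;
  // Multimodal Laplace: run the damped Newton from every start, keep the
  // distinct modes found (deduplicated within 0.05 in eta space), and sum
  // their Laplace contributions. Summing - rather than taking the best
  // mode - keeps the marginal continuous in the population parameters when
  // a subject's conditional posterior has nearly-tied modes.
  std::vector<arma::vec> modes;
  std::vector<double> fvals;
  std::vector<bool> convs;
  for (arma::uword s = 0; s < eta_starts.n_cols; ++s) {
    arma::vec eta = eta_starts.col(s);
    double f = NLL(eta);
    if (!std::isfinite(f)) continue;
    double lambda = 1e-4;
    bool conv = false;
    for (int it = 0; it < max_iter; ++it) {
      arma::vec g = fd_grad(eta, 1e-6, t, dv, blq, lloq, occ, dose, ii,
                            logtyp, map, omega2, a, b, mix_kappa, mix_logw, mix2_kappa, mix2_logw);
      if (arma::norm(g, 2) < tol) { conv = true; break; }
      arma::mat H = fd_hess(eta, fdh, t, dv, blq, lloq, occ, dose, ii,
                            logtyp, map, omega2, a, b, mix_kappa, mix_logw, mix2_kappa, mix2_logw);
      bool stepped = false;
      for (int k = 0; k < 12; ++k) {
        arma::mat Hd = H + lambda * arma::eye(d, d);
        arma::vec step;
        bool ok = arma::solve(step, Hd, -g, arma::solve_opts::no_approx);
        if (ok) {
          arma::vec cand = eta + step;
          double fc = NLL(cand);
          if (std::isfinite(fc) && fc < f) {
            eta = cand; f = fc; lambda = std::max(lambda / 3.0, 1e-8);
            stepped = true;
            break;
          }
        }
        lambda *= 10.0;
      }
      if (!stepped) break;  // cannot improve further (noise floor)
    }
    if (!conv) {
      arma::vec g = fd_grad(eta, 1e-6, t, dv, blq, lloq, occ, dose, ii,
                            logtyp, map, omega2, a, b, mix_kappa, mix_logw, mix2_kappa, mix2_logw);
      conv = arma::norm(g, 2) < std::max(tol, 1e-3);
    }
    bool dup = false;
    for (size_t k = 0; k < modes.size(); ++k) {
      bool same = arma::norm(eta - modes[k], 2) < 0.05;
      if (!same) {
        // no barrier at the midpoint means the two points share a basin
        // (a stalled search along a flat valley is not a second mode)
        arma::vec mid = 0.5 * (eta + modes[k]);
        double fm = NLL(mid);
        same = std::isfinite(fm) && fm <= std::max(f, fvals[k]) + 0.1;
      }
      if (same) {
        dup = true;
        if (f < fvals[k]) { modes[k] = eta; fvals[k] = f; convs[k] = conv; }
        break;
      }
    }
    if (!dup) { modes.push_back(eta); fvals.push_back(f); convs.push_back(conv); }
  }
  if (modes.empty()) {
    return List::create(_["nll"] = R_PosInf,
                        _["eta"] = NumericVector(d, 0.0),
                        _["hess"] = NumericMatrix(d, d), _["conv"] = false);
  }
  std::vector<double> gvals(modes.size());
  std::vector<arma::mat> hmats(modes.size());
  bool all_ok = true;
  size_t kbest = 0;
  for (size_t k = 0; k < modes.size(); ++k) {
    arma::mat H = fd_hess(modes[k], fdh, t, dv, blq, lloq, occ, dose, ii,
                          logtyp, map, omega2, a, b, mix_kappa, mix_logw, mix2_kappa, mix2_logw);
    arma::mat L;
    double ridge = 0.0;
    bool ok = arma::chol(L, H, "lower");
    while (!ok && ridge < 1e6) {
      ridge = (ridge == 0.0) ? 1e-8 : ridge * 100.0;
      ok = arma::chol(L, H + ridge * arma::eye(d, d), "lower");
    }
    if (!ok) all_ok = false;
    double logdet = ok ? 2.0 * arma::accu(arma::log(L.diag())) : R_PosInf;
    gvals[k] = fvals[k] - 0.5 * d * std::log(2.0 * M_PI) + 0.5 * logdet;
    hmats[k] = H;
    if (gvals[k] < gvals[kbest]) kbest = k;
  }
  double acc = 0.0;
  for (size_t k = 0; k < modes.size(); ++k)
    acc += std::exp(gvals[kbest] - gvals[k]);
  double marg = gvals[kbest] - std::log(acc);
  return List::create(_["nll"] = marg,
                      _["eta"] = NumericVector(modes[kbest].begin(), modes[kbest].end()),
                      _["hess"] = wrap(hmats[kbest]),
                      _["conv"] = convs[kbest] && all_ok);
}

// vectorised single-dose / steady-state concentration (simulation hot path)
// [[Rcpp::export(name = ".cpp_conc1lag")]]
NumericVector cpp_conc1lag(const NumericVector& t, const NumericVector& dose,
                           const NumericVector& F, const NumericVector& CL,
                           const NumericVector& V, const NumericVector& ka,
                           const NumericVector& tlag, const LogicalVector& ss,
                           double ii) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double tred = t[i] - ii * std::floor(t[i] / ii);  // t mod ii
    out[i] = ss[i]
      ? conc1lag_ss(tred, ii, dose[i], F[i], CL[i], V[i], ka[i], tlag[i])
      : conc1lag(t[i], dose[i], F[i], CL[i], V[i], ka[i], tlag[i]);
  }
  return out;
}

// Specialised fast marginal for the quadrature-mixture configuration: both
// absorption effects (lag, and absorption rate when present) are mixture
// components fixed during the inner optimisation, so the per-component
// exponentials exp(-ka_l (t_i - tlag_k)) can be tabulated once per call and
// the inner Newton over the remaining (F, CL, V) dimensions reuses them.
// Requires: no random effect on ka or tlag in the Laplace block.
// [[Rcpp::export(name = ".cpp_onecpt_laplace_fast")]]
List cpp_onecpt_laplace_fast(const arma::mat& eta_starts,
                             const NumericVector& t, const NumericVector& dv,
                             const LogicalVector& blq,
                             const NumericVector& lloq,
                             const IntegerVector& occ, double dose, double ii,
                             const arma::vec& logtyp,
                             const IntegerMatrix& map,
                             const arma::vec& omega2, double a, double b,
                             const arma::vec& mix_kappa,
                             const arma::vec& mix_logw,
                             const arma::vec& mix2_kappa,
                             const arma::vec& mix2_logw, double tol = 1e-6,
                             int max_iter = 100) {
  arma::uword d = eta_starts.n_rows;
  // split observations
  std::vector<int> iint, ipre;
  for (int i = 0; i < t.size(); ++i) {
    if (occ[i] == 1) ipre.push_back(i); else iint.push_back(i);
  }
  arma::uword ni = iint.size();
  arma::uword K1 = std::max((arma::uword)mix_kappa.n_elem, (arma::uword)1);
  arma::uword K2 = std::max((arma::uword)mix2_kappa.n_elem, (arma::uword)1);
  bool hasK1 = mix_kappa.n_elem > 0, hasK2 = mix2_kappa.n_elem > 0;
  // component parameter values (typical scale; no eta on ka/tlag)
  arma::vec tlagk(K1), kal(K2), lwk(K1), lwl(K2);
  for (arma::uword k = 0; k < K1; ++k) {
    tlagk(k) = std::exp(logtyp(4) + (hasK1 ? mix_kappa(k) : 0.0));
    lwk(k) = hasK1 ? mix_logw(k) : 0.0;
  }
  for (arma::uword l = 0; l < K2; ++l) {
    kal(l) = std::exp(logtyp(3) + (hasK2 ? mix2_kappa(l) : 0.0));
    lwl(l) = hasK2 ? mix2_logw(l) : 0.0;
  }
  // tables: tau, mask, exp(-ka_l * tau_ik)
  arma::cube P2(ni, K1, K2);
  arma::mat tau(ni, K1);
  for (arma::uword i = 0; i < ni; ++i) {
    double ti = t[iint[i]];
    for (arma::uword k = 0; k < K1; ++k) {
      tau(i, k) = ti - tlagk(k);
      for (arma::uword l = 0; l < K2; ++l) {
        P2(i, k, l) = tau(i, k) > 0 ? std::exp(-kal(l) * tau(i, k)) : 0.0;
      }
    }
  }
  const double log2pi = std::log(2.0 * M_PI);
  // joint nll as a function of the Laplace-block eta
  auto nllf = [&](const arma::vec& eta) -> double {
    arma::vec lp1 = logtyp, lp2 = logtyp;
    for (arma::uword j = 0; j < eta.n_elem; ++j) {
      int p = map(j, 0), oc = map(j, 1);
      if (oc == 0) { lp1(p) += eta(j); lp2(p) += eta(j); }
      else if (oc == 1) lp1(p) += eta(j);
      else lp2(p) += eta(j);
    }
    double nll = 0.0;
    // predose: steady-state trough at typical absorption
    if (!ipre.empty()) {
      double F1 = std::exp(lp1(0)), CL1 = std::exp(lp1(1)),
             V1 = std::exp(lp1(2)), ka1 = std::exp(lp1(3)),
             tl1 = std::exp(lp1(4));
      double pred = conc1lag_ss(ii, ii, dose, F1, CL1, V1, ka1, tl1);
      for (int idx : ipre)
        nll += obs_nll_1(dv[idx], blq[idx], lloq[idx], pred, a, b);
    }
    if (ni > 0) {
      double F2 = std::exp(lp2(0)), CL2 = std::exp(lp2(1)),
             V2 = std::exp(lp2(2));
      double ke = CL2 / V2;
      arma::vec xi(ni), yk(K1);
      for (arma::uword i = 0; i < ni; ++i) xi(i) = std::exp(-ke * t[iint[i]]);
      for (arma::uword k = 0; k < K1; ++k) yk(k) = std::exp(ke * tlagk(k));
      double best = -1e300;
      arma::mat lcomp(K1, K2);
      for (arma::uword l = 0; l < K2; ++l) {
        double dk = kal(l) - ke;
        bool equal_rates = std::fabs(dk) / ke < 1e-6;
        double A = F2 * dose * kal(l) / (V2 * dk);
        for (arma::uword k = 0; k < K1; ++k) {
          double ll = 0.0;
          for (arma::uword i = 0; i < ni; ++i) {
            double pred;
            if (tau(i, k) <= 0) pred = 0.0;
            else if (equal_rates)
              pred = F2 * dose * kal(l) * tau(i, k) *
                     std::exp(-kal(l) * tau(i, k)) / V2;
            else pred = A * (xi(i) * yk(k) - P2(i, k, l));
            int idx = iint[i];
            if (blq[idx]) {
              double sd = std::sqrt(a * a + b * b * pred * pred);
              ll += R::pnorm(lloq[idx], pred, sd, 1, 1);
            } else {
              double s2 = a * a + b * b * pred * pred;
              double r = dv[idx] - pred;
              ll -= 0.5 * (log2pi + std::log(s2) + r * r / s2);
            }
          }
          double v = lwk(k) + lwl(l) + ll;
          lcomp(k, l) = v;
          if (v > best) best = v;
        }
      }
      double acc = 0.0;
      for (arma::uword l = 0; l < K2; ++l)
        for (arma::uword k = 0; k < K1; ++k)
          acc += std::exp(lcomp(k, l) - best);
      nll -= best + std::log(acc);
    }
    for (arma::uword j = 0; j < eta.n_elem; ++j)
      nll += 0.5 * (eta(j) * eta(j) / omega2(j) +
                    std::log(2.0 * M_PI * omega2(j)));
    return nll;
  };
  if (d == 0) {
    arma::vec e0;
    double f0 = nllf(e0);
    return List::create(_["nll"] = f0, _["eta"] = NumericVector(0),
                        _["hess"] = NumericMatrix(0, 0), _["conv"] = true);
  }
  auto gradf = [&](const arma::vec& eta) {
    arma::vec g(d);
    for (arma::uword j = 0; j < d; ++j) {
      double hj = 1e-6 * std::max(1.0, std::fabs(eta(j)));
      arma::vec ep = eta, em = eta;
      ep(j) += hj; em(j) -= hj;
      g(j) = (nllf(ep) - nllf(em)) / (2.0 * hj);
    }
    return g;
  };
  auto hessf = [&](const arma::vec& eta) {
    arma::mat H(d, d);
    const double h = 1e-4;
    for (arma::uword i = 0; i < d; ++i) {
      double hi = h * std::max(1.0, std::fabs(eta(i)));
      for (arma::uword j = 0; j <= i; ++j) {
        double hj = h * std::max(1.0, std::fabs(eta(j)));
        arma::vec epp = eta, epm = eta, emp = eta, emm = eta;
        epp(i) += hi; epp(j) += hj;
        epm(i) += hi; epm(j) -= hj;
        emp(i) -= hi; emp(j) += hj;
        emm(i) -= hi; emm(j) -= hj;
        H(i, j) = H(j, i) = (nllf(epp) - nllf(epm) - nllf(emp) + nllf(emm)) /
                            (4.0 * hi * hj);
      }
    }
    return H;
  };
  // screen the candidate starts on value alone, then run one damped Newton
  // from the best; the Hessian is reused across iterations and refreshed
  // only every third step or when a step fails
  arma::uword s_best = 0;
  double f_screen = R_PosInf;
  for (arma::uword s = 0; s < eta_starts.n_cols; ++s) {
    double fs = nllf(eta_starts.col(s));
    if (std::isfinite(fs) && fs < f_screen) { f_screen = fs; s_best = s; }
  }
  arma::vec best_eta = eta_starts.col(s_best);
  double best_f = f_screen;
  bool best_conv = false;
  if (std::isfinite(best_f)) {
    arma::vec eta = best_eta;
    double f = best_f;
    double lambda = 1e-4;
    bool conv = false;
    arma::mat H;
    bool haveH = false;
    for (int it = 0; it < max_iter; ++it) {
      arma::vec g = gradf(eta);
      if (arma::norm(g, 2) < tol) { conv = true; break; }
      if (!haveH || it % 3 == 2) { H = hessf(eta); haveH = true; }
      bool stepped = false;
      for (int k = 0; k < 12; ++k) {
        arma::vec step;
        bool ok = arma::solve(step, H + lambda * arma::eye(d, d), -g,
                              arma::solve_opts::no_approx);
        if (ok) {
          arma::vec cand = eta + step;
          double fc = nllf(cand);
          if (std::isfinite(fc) && fc < f) {
            eta = cand; f = fc; lambda = std::max(lambda / 3.0, 1e-8);
            stepped = true;
            break;
          }
        }
        if (k == 2 && it % 3 != 2) { H = hessf(eta); }  // stale Hessian retry
        lambda *= 10.0;
      }
      if (!stepped) break;
    }
    if (!conv) conv = arma::norm(gradf(eta), 2) < std::max(tol, 1e-3);
    best_f = f; best_eta = eta; best_conv = conv;
  }
  if (!std::isfinite(best_f)) {
    return List::create(_["nll"] = R_PosInf,
                        _["eta"] = NumericVector(d, 0.0),
                        _["hess"] = NumericMatrix(d, d), _["conv"] = false);
  }
  arma::mat H = hessf(best_eta);
  arma::mat L;
  double ridge = 0.0;
  bool ok = arma::chol(L, H, "lower");
  while (!ok && ridge < 1e6) {
    ridge = (ridge == 0.0) ? 1e-8 : ridge * 100.0;
    ok = arma::chol(L, H + ridge * arma::eye(d, d), "lower");
  }
  double logdet = ok ? 2.0 * arma::accu(arma::log(L.diag())) : R_PosInf;
  double marg = best_f - 0.5 * d * std::log(2.0 * M_PI) + 0.5 * logdet;
  return List::create(_["nll"] = marg,
                      _["eta"] = NumericVector(best_eta.begin(), best_eta.end()),
                      _["hess"] = wrap(H), _["conv"] = best_conv && ok);
}
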