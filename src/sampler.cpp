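// Metropolis-within-Gibbs sampler for the three multilevel ecological
// regression variants.
//
// Tract level:  O_i ~ Poisson(E_i exp(eta_i)),
//               eta_i = b1[c_i] + b2[c_i] X_i + S_i + H_i
// S: intrinsic CAR per city under the per-component sum-to-zero
//    identifiability constraint.  Single-site proposals move along
//    e_i - 1/m (m = component size), i.e. the proposed site change is
//    balanced by an opposite shift spread over its component, so every
//    proposal stays exactly on the constraint manifold and the
//    constrained ICAR x likelihood target is preserved exactly (the
//    aggregate likelihood change needs only the component's count and
//    E*exp(eta) totals, so the move costs O(1) plus O(m) on acceptance).
// H: iid Normal(0, sigH[city]^2).
// City coefficients b1, b2: flat (M1), exchangeable normal (M2), or
// multivariate normal with exponential distance-decay covariance (M3).
// Standard deviations: Uniform(0, l) priors, updated by conjugate Gibbs
// steps on the variance (truncated inverse-gamma via the gamma quantile
// function).  Decay parameters: Uniform(a, b), random-walk Metropolis.
// alpha/beta: conjugate Gibbs (flat or Normal(0, sd0^2) prior).
//
// Proposal scales adapt toward 44% acceptance during burn-in only and are
// frozen afterwards, so the retained draws come from a fixed kernel.
//
// Uses R's RNG throughout: runs are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double dlik(double O, double E, double eta, double d) {
  return O * d - E * (std::exp(eta + d) - std::exp(eta));
}

// sigma | rest  with  p(sigma) ~ sigma^{-n} exp(-q/(2 sigma^2)) on (0, l).
// For n >= 2 this is a truncated inverse-gamma on sigma^2, sampled exactly
// through the gamma quantile function on the precision scale; otherwise a
// uniform-proposal independence Metropolis step keeps the chain correct.
static double update_sd(double cur, double n, double q, double l) {
  double shape = (n - 1.0) / 2.0;
  if (shape > 0.0 && q > 0.0) {
    double scale = 2.0 / q;               // gamma scale for the precision
    double glo = 1.0 / (l * l);
    double plo = R::pgamma(glo, shape, scale, 1, 0);
    if (plo > 1.0 - 1e-12) {
      // posterior mass wants sigma > l; pin just inside the bound
      return l * (1.0 - 1e-8);
    }
    double u = R::runif(plo, 1.0);
    if (u >= 1.0) u = 1.0 - 1e-16;
    double g = R::qgamma(u, shape, scale, 1, 0);
    if (g < glo) g = glo * (1.0 + 1e-12);
    return 1.0 / std::sqrt(g);
  }
  // degenerate exponent: independence MH with Uniform(0,l) proposal
  double prop = R::runif(0.0, l);
  double lr = -n * (std::log(prop) - std::log(cur))
              - q / 2.0 * (1.0 / (prop * prop) - 1.0 / (cur * cur));
  if (std::log(R::runif(0.0, 1.0)) < lr) return prop;
  return cur;
}

struct CorrState {
  arma::mat Rinv;
  double logdet;
  bool ok;
};

static CorrState corr_state(const arma::mat &D, double phi) {
  CorrState cs; cs.ok = false;
  arma::mat R = arma::exp(-phi * D);
  arma::mat ch;
  if (!arma::chol(ch, R)) return cs;
  cs.logdet = 2.0 * arma::accu(arma::log(ch.diag()));
  arma::mat chi = arma::inv(arma::trimatu(ch));
  cs.Rinv = chi * chi.t();
  cs.ok = true;
  return cs;
}

// [[Rcpp::export(name = ".svc_sampler")]]
List svc_sampler(NumericVector O_, NumericVector E_, NumericVector X_,
                 IntegerVector city_, int J,
                 IntegerVector adj_ptr_, IntegerVector adj_idx_,
                 IntegerVector comp_, int nComp,
                 arma::mat D,
                 int variant, double l, double phiLo, double phiHi,
                 double coefPriorSd,
                 bool includeIcar, bool includeHet, bool useLik,
                 int nIter, int nBurnin, int thin, bool adapt,
                 List init, List scalesIn) {
  const int N = O_.size();
  arma::vec O(O_.begin(), N), E(E_.begin(), N), X(X_.begin(), N);
  arma::vec logE = arma::log(E);
  std::vector<int> city(city_.begin(), city_.end());
  std::vector<int> adj_ptr(adj_ptr_.begin(), adj_ptr_.end());
  std::vector<int> adj_idx(adj_idx_.begin(), adj_idx_.end());
  std::vector<int> comp(comp_.begin(), comp_.end());

  // city block boundaries (tracts are sorted by city)
  std::vector<int> cstart(J, -1), cend(J, -1), nj(J, 0);
  for (int i = 0; i < N; ++i) {
    if (cstart[city[i]] < 0) cstart[city[i]] = i;
    cend[city[i]] = i + 1;
    nj[city[i]] += 1;
  }
  // components per city and component sizes / member lists
  std::vector<int> compSize(nComp, 0), compCity(nComp, -1);
  for (int i = 0; i < N; ++i) { compSize[comp[i]]++; compCity[comp[i]] = city[i]; }
  std::vector< std::vector<int> > compMembers(nComp);
  for (int i = 0; i < N; ++i) compMembers[comp[i]].push_back(i);
  arma::vec compSumO(nComp, arma::fill::zeros);
  for (int i = 0; i < N; ++i) compSumO[comp[i]] += O[i];
  std::vector<int> cityComps(J, 0);
  for (int c = 0; c < nComp; ++c) cityComps[compCity[c]]++;
  // effective ICAR dimension per city: n_j - c_j
  std::vector<double> nEff(J);
  for (int j = 0; j < J; ++j) nEff[j] = nj[j] - cityComps[j];

  double prec0 = (R_FINITE(coefPriorSd)) ? 1.0 / (coefPriorSd * coefPriorSd) : 0.0;

  // ---- state ----
  auto getv = [&](const char *nm, int len, double def) {
    if (init.containsElementNamed(nm)) {
      NumericVector v = init[nm];
      return arma::vec(v.begin(), len);
    }
    return arma::vec(len, arma::fill::value(def));
  };
  auto gets = [&](const char *nm, double def) {
    if (init.containsElementNamed(nm)) return as<double>(init[nm]);
    return def;
  };
  arma::vec b1 = getv("b1", J, 0.0), b2 = getv("b2", J, 0.0);
  arma::vec S = getv("S", N, 0.0), H = getv("H", N, 0.0);
  arma::vec sigS = getv("sigmaS", J, 0.1), sigH = getv("sigmaH", J, 0.1);
  double alpha = gets("alpha", 0.0), beta = gets("beta", 0.0);
  double sigB1 = gets("sigmaB1", 0.1), sigB2 = gets("sigmaB2", 0.05);
  double sig1 = gets("sigma1", 0.1), sig2 = gets("sigma2", 0.05);
  double phi1 = gets("phi1", 0.5 * (phiLo + phiHi));
  double phi2 = gets("phi2", 0.5 * (phiLo + phiHi));

  CorrState cs1, cs2;
  if (variant == 3) {
    cs1 = corr_state(D, phi1);
    cs2 = corr_state(D, phi2);
    if (!cs1.ok || !cs2.ok) stop("initial correlation matrix not positive definite");
  }

  arma::vec eta(N);
  for (int i = 0; i < N; ++i)
    eta[i] = b1[city[i]] + b2[city[i]] * X[i] + S[i] + H[i];

  // ---- proposal scales ----
  auto getsc = [&](const char *nm, int len, double def) {
    if (scalesIn.containsElementNamed(nm)) {
      NumericVector v = scalesIn[nm];
      return arma::vec(v.begin(), len);
    }
    return arma::vec(len, arma::fill::value(def));
  };
  arma::vec scS = getsc("S", N, 0.3), scH = getsc("H", N, 0.3);
  arma::vec scB1 = getsc("b1", J, 0.1), scB2 = getsc("b2", J, 0.02);
  arma::vec scPhi = getsc("phi", 2, 0.1 * (phiHi - phiLo));
  arma::vec scSwap = getsc("swap", J, 0.1);      // b1 <-> mean(H) swap
  arma::vec scLvl = getsc("level", 2, 0.05);     // global alpha/beta shifts
  arma::vec scSS = getsc("sScale", J, 0.3);      // joint (S, sigmaS) rescale
  arma::vec scHS = getsc("hScale", J, 0.3);      // joint (H, sigmaH) rescale

  arma::vec accS(N, arma::fill::zeros), accH(N, arma::fill::zeros);
  arma::vec accB1(J, arma::fill::zeros), accB2(J, arma::fill::zeros);
  arma::vec accPhi(2, arma::fill::zeros);
  arma::vec accSwap(J, arma::fill::zeros), accLvl(2, arma::fill::zeros);
  arma::vec accSS(J, arma::fill::zeros), accHS(J, arma::fill::zeros);
  double postAccS = 0, postAccH = 0, postAccB1 = 0, postAccB2 = 0;
  double postAccPhi = 0, postSweeps = 0;

  const int batch = 50;
  int batchNum = 0;

  // ---- output ----
  int nKeep = (nIter - nBurnin) / thin;
  if (nKeep < 0) nKeep = 0;
  int extras = (variant == 1) ? 0 : ((variant == 2) ? 4 : 6);
  int P = 4 * J + extras;
  arma::mat samples(nKeep, P);
  arma::vec devOut(nKeep);
  arma::vec logThetaSum(N, arma::fill::zeros);
  double devConst = 0.0;
  for (int i = 0; i < N; ++i) devConst += std::lgamma(O[i] + 1.0);
  int keep = 0;

  for (int t = 1; t <= nIter; ++t) {
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
    // ---- S: constraint-preserving single-site MH ----
    if (includeIcar) {
      // component totals of E * exp(eta), maintained through the sweep
      arma::vec compEexp(nComp, arma::fill::zeros);
      if (useLik)
        for (int i = 0; i < N; ++i) compEexp[comp[i]] += E[i] * std::exp(eta[i]);
      for (int i = 0; i < N; ++i) {
        int nnb = adj_ptr[i + 1] - adj_ptr[i];
        if (nnb == 0) continue;           // isolated: pinned at 0
        int c = comp[i];
        int m = compSize[c];
        if (m < 2) continue;
        int j = city[i];
        double d = scS[i] * R::rnorm(0.0, 1.0);
        // proposal S -> S + d*(e_i - 1/m within component)
        double nbsum = 0.0;
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) nbsum += S[adj_idx[k]];
        double Qs_i = nnb * S[i] - nbsum;
        double dpri = -(2.0 * d * Qs_i + d * d * nnb) / (2.0 * sigS[j] * sigS[j]);
        double dl = 0.0;
        double Eexp_i = 0.0, a1 = 0.0, a2 = 0.0;
        if (useLik) {
          Eexp_i = E[i] * std::exp(eta[i]);
          a1 = std::expm1(d * (1.0 - 1.0 / m));
          a2 = std::expm1(-d / m);
          dl = O[i] * d - (d / m) * compSumO[c]
               - Eexp_i * a1 - (compEexp[c] - Eexp_i) * a2;
        }
        if (std::log(R::runif(0.0, 1.0)) < dl + dpri) {
          double shift = d / m;
          const std::vector<int> &mem = compMembers[c];
          for (size_t k = 0; k < mem.size(); ++k) {
            S[mem[k]] -= shift; eta[mem[k]] -= shift;
          }
          S[i] += d; eta[i] += d;
          if (useLik)
            compEexp[c] = (compEexp[c] - Eexp_i) * (1.0 + a2) + Eexp_i * (1.0 + a1);
          accS[i] += 1.0;
        }
      }
      // numerical hygiene: project out float drift from the constraint
      arma::vec cmean(nComp, arma::fill::zeros);
      for (int i = 0; i < N; ++i) cmean[comp[i]] += S[i];
      for (int c = 0; c < nComp; ++c) cmean[c] /= compSize[c];
      for (int i = 0; i < N; ++i) {
        S[i] -= cmean[comp[i]];
        eta[i] -= cmean[comp[i]];
      }
    }

    // ---- H (single-site MH) ----
    if (includeHet) {
      for (int i = 0; i < N; ++i) {
        int j = city[i];
        double h = H[i];
        double d = scH[i] * R::rnorm(0.0, 1.0);
        double hp = h + d;
        double dpri = -(hp * hp - h * h) / (2.0 * sigH[j] * sigH[j]);
        double dl = useLik ? dlik(O[i], E[i], eta[i], d) : 0.0;
        if (std::log(R::runif(0.0, 1.0)) < dl + dpri) {
          H[i] = hp; eta[i] += d; accH[i] += 1.0;
        }
      }
    }

    // ---- b1, b2 (per-city MH) ----
    for (int j = 0; j < J; ++j) {
      // b1[j]
      {
        double d = scB1[j] * R::rnorm(0.0, 1.0);
        double dl = 0.0;
        if (useLik)
          for (int i = cstart[j]; i < cend[j]; ++i) dl += dlik(O[i], E[i], eta[i], d);
        double dpri = 0.0;
        double bj = b1[j], bp = bj + d;
        if (variant == 2) {
          dpri = -((bp - alpha) * (bp - alpha) - (bj - alpha) * (bj - alpha)) /
                 (2.0 * sigB1 * sigB1);
        } else if (variant == 3) {
          double rowdot = arma::dot(cs1.Rinv.row(j).t(), b1 - alpha);
          double Pjj = cs1.Rinv(j, j);
          double cross = rowdot - Pjj * (bj - alpha);
          dpri = -(Pjj * ((bp - alpha) * (bp - alpha) - (bj - alpha) * (bj - alpha))
                   + 2.0 * d * cross) / (2.0 * sig1 * sig1);
        }
        if (std::log(R::runif(0.0, 1.0)) < dl + dpri) {
          b1[j] = bp;
          for (int i = cstart[j]; i < cend[j]; ++i) eta[i] += d;
          accB1[j] += 1.0;
        }
      }
      // b2[j]
      {
        double d = scB2[j] * R::rnorm(0.0, 1.0);
        double dl = 0.0;
        if (useLik)
          for (int i = cstart[j]; i < cend[j]; ++i)
            dl += dlik(O[i], E[i], eta[i], d * X[i]);
        double dpri = 0.0;
        double bj = b2[j], bp = bj + d;
        if (variant == 2) {
          dpri = -((bp - beta) * (bp - beta) - (bj - beta) * (bj - beta)) /
                 (2.0 * sigB2 * sigB2);
        } else if (variant == 3) {
          double rowdot = arma::dot(cs2.Rinv.row(j).t(), b2 - beta);
          double Pjj = cs2.Rinv(j, j);
          double cross = rowdot - Pjj * (bj - beta);
          dpri = -(Pjj * ((bp - beta) * (bp - beta) - (bj - beta) * (bj - beta))
                   + 2.0 * d * cross) / (2.0 * sig2 * sig2);
        }
        if (std::log(R::runif(0.0, 1.0)) < dl + dpri) {
          b2[j] = bp;
          for (int i = cstart[j]; i < cend[j]; ++i) eta[i] += d * X[i];
          accB2[j] += 1.0;
        }
      }
    }

    // ---- reparameterization swap: b1[j] + d, H (city j) - d ----
    // Likelihood-invariant; breaks the BYM aliasing between the city
    // intercept and the mean of its heterogeneity effects.
    if (includeHet) {
      for (int j = 0; j < J; ++j) {
        double d = scSwap[j] * R::rnorm(0.0, 1.0);
        double hsum = 0.0;
        for (int i = cstart[j]; i < cend[j]; ++i) hsum += H[i];
        double dpri = -(nj[j] * d * d - 2.0 * d * hsum) /
                      (2.0 * sigH[j] * sigH[j]);
        double bj = b1[j], bp = bj + d;
        if (variant == 2) {
          dpri += -((bp - alpha) * (bp - alpha) - (bj - alpha) * (bj - alpha)) /
                  (2.0 * sigB1 * sigB1);
        } else if (variant == 3) {
          double rowdot = arma::dot(cs1.Rinv.row(j).t(), b1 - alpha);
          double Pjj = cs1.Rinv(j, j);
          double cross = rowdot - Pjj * (bj - alpha);
          dpri += -(Pjj * ((bp - alpha) * (bp - alpha) - (bj - alpha) * (bj - alpha))
                    + 2.0 * d * cross) / (2.0 * sig1 * sig1);
        }
        if (std::log(R::runif(0.0, 1.0)) < dpri) {
          b1[j] = bp;
          for (int i = cstart[j]; i < cend[j]; ++i) H[i] -= d;
          accSwap[j] += 1.0;
        }
      }
    }

    // ---- global level shifts of (alpha, b1) and (beta, b2) ----
    // b - mean residuals are held fixed, so the coefficient prior is
    // unchanged and only the likelihood (and any proper prior on
    // alpha/beta) enters the ratio.  Mixes the overall level, which the
    // tight Gibbs step for alpha/beta given b cannot move on its own.
    if (variant != 1) {
      {
        double d = scLvl[0] * R::rnorm(0.0, 1.0);
        double dl = 0.0;
        if (useLik) for (int i = 0; i < N; ++i) dl += dlik(O[i], E[i], eta[i], d);
        double dpri = (prec0 > 0)
          ? -((alpha + d) * (alpha + d) - alpha * alpha) * prec0 / 2.0 : 0.0;
        if (std::log(R::runif(0.0, 1.0)) < dl + dpri) {
          alpha += d; b1 += d; eta += d; accLvl[0] += 1.0;
        }
      }
      {
        double d = scLvl[1] * R::rnorm(0.0, 1.0);
        double dl = 0.0;
        if (useLik) for (int i = 0; i < N; ++i) dl += dlik(O[i], E[i], eta[i], d * X[i]);
        double dpri = (prec0 > 0)
          ? -((beta + d) * (beta + d) - beta * beta) * prec0 / 2.0 : 0.0;
        if (std::log(R::runif(0.0, 1.0)) < dl + dpri) {
          beta += d; b2 += d; eta += d * X; accLvl[1] += 1.0;
        }
      }
    }

    // ---- alpha, beta (Gibbs; M2/M3 only) ----
    if (variant == 2) {
      double prec = J / (sigB1 * sigB1) + prec0;
      double mu = (arma::accu(b1) / (sigB1 * sigB1)) / prec;
      alpha = mu + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      prec = J / (sigB2 * sigB2) + prec0;
      mu = (arma::accu(b2) / (sigB2 * sigB2)) / prec;
      beta = mu + R::rnorm(0.0, 1.0) / std::sqrt(prec);
    } else if (variant == 3) {
      arma::vec w1 = cs1.Rinv * arma::ones(J);
      double prec = arma::accu(w1) / (sig1 * sig1) + prec0;
      double mu = (arma::dot(w1, b1) / (sig1 * sig1)) / prec;
      alpha = mu + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      arma::vec w2 = cs2.Rinv * arma::ones(J);
      prec = arma::accu(w2) / (sig2 * sig2) + prec0;
      mu = (arma::dot(w2, b2) / (sig2 * sig2)) / prec;
      beta = mu + R::rnorm(0.0, 1.0) / std::sqrt(prec);
    }

    // ---- joint (field, sd) scale moves ----
    // Multiply a city's random-effect field and its standard deviation by
    // the same factor exp(u): the field prior density is invariant up to
    // the Jacobian, so the ratio reduces to the likelihood change plus u.
    // Moves the spatial-vs-unstructured variance split, which single-site
    // updates traverse very slowly.
    if (includeIcar) {
      for (int j = 0; j < J; ++j) {
        if (nEff[j] <= 0) continue;
        double u = scSS[j] * R::rnorm(0.0, 1.0);
        double cfac = std::exp(u);
        if (sigS[j] * cfac >= l) continue;
        double dl = 0.0;
        if (useLik)
          for (int i = cstart[j]; i < cend[j]; ++i)
            dl += dlik(O[i], E[i], eta[i], (cfac - 1.0) * S[i]);
        if (std::log(R::runif(0.0, 1.0)) < dl + u) {
          for (int i = cstart[j]; i < cend[j]; ++i) {
            eta[i] += (cfac - 1.0) * S[i];
            S[i] *= cfac;
          }
          sigS[j] *= cfac;
          accSS[j] += 1.0;
        }
      }
    }
    if (includeHet) {
      for (int j = 0; j < J; ++j) {
        double u = scHS[j] * R::rnorm(0.0, 1.0);
        double cfac = std::exp(u);
        if (sigH[j] * cfac >= l) continue;
        double dl = 0.0;
        if (useLik)
          for (int i = cstart[j]; i < cend[j]; ++i)
            dl += dlik(O[i], E[i], eta[i], (cfac - 1.0) * H[i]);
        if (std::log(R::runif(0.0, 1.0)) < dl + u) {
          for (int i = cstart[j]; i < cend[j]; ++i) {
            eta[i] += (cfac - 1.0) * H[i];
            H[i] *= cfac;
          }
          sigH[j] *= cfac;
          accHS[j] += 1.0;
        }
      }
    }

    // ---- variance parameters ----
    if (includeIcar) {
      for (int j = 0; j < J; ++j) {
        if (nEff[j] <= 0) { sigS[j] = R::runif(0.0, l); continue; }
        double q = 0.0;
        for (int i = cstart[j]; i < cend[j]; ++i)
          for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
            int m = adj_idx[k];
            if (m > i) { double dd = S[i] - S[m]; q += dd * dd; }
          }
        sigS[j] = update_sd(sigS[j], nEff[j], q, l);
      }
    }
    if (includeHet) {
      for (int j = 0; j < J; ++j) {
        double q = 0.0;
        for (int i = cstart[j]; i < cend[j]; ++i) q += H[i] * H[i];
        sigH[j] = update_sd(sigH[j], (double)nj[j], q, l);
      }
    }
    if (variant == 2) {
      sigB1 = update_sd(sigB1, (double)J, arma::accu(arma::square(b1 - alpha)), l);
      sigB2 = update_sd(sigB2, (double)J, arma::accu(arma::square(b2 - beta)), l);
    } else if (variant == 3) {
      arma::vec r1 = b1 - alpha, r2 = b2 - beta;
      double q1 = arma::as_scalar(r1.t() * cs1.Rinv * r1);
      double q2 = arma::as_scalar(r2.t() * cs2.Rinv * r2);
      sig1 = update_sd(sig1, (double)J, q1, l);
      sig2 = update_sd(sig2, (double)J, q2, l);
      // ---- decay parameters (RW Metropolis within (a, b)) ----
      for (int f = 0; f < 2; ++f) {
        double &phi = (f == 0) ? phi1 : phi2;
        double sig = (f == 0) ? sig1 : sig2;
        CorrState &cs = (f == 0) ? cs1 : cs2;
        arma::vec r = (f == 0) ? r1 : r2;
        double prop = phi + scPhi[f] * R::rnorm(0.0, 1.0);
        if (prop > phiLo && prop < phiHi) {
          CorrState csp = corr_state(D, prop);
          if (csp.ok) {
            double qc = arma::as_scalar(r.t() * cs.Rinv * r);
            double qp = arma::as_scalar(r.t() * csp.Rinv * r);
            double lr = -0.5 * (csp.logdet - cs.logdet)
                        - (qp - qc) / (2.0 * sig * sig);
            if (std::log(R::runif(0.0, 1.0)) < lr) {
              phi = prop; cs = csp; accPhi[f] += 1.0;
            }
          }
        }
      }
    }

    // ---- adaptation (burn-in only) ----
    if (adapt && t <= nBurnin && t % batch == 0) {
      batchNum++;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batchNum));
      auto tune = [&](arma::vec &sc, arma::vec &acc) {
        for (arma::uword k = 0; k < sc.n_elem; ++k) {
          double rate = acc[k] / batch;
          sc[k] *= std::exp(rate > 0.44 ? delta : -delta);
          acc[k] = 0.0;
        }
      };
      tune(scS, accS); tune(scH, accH); tune(scB1, accB1); tune(scB2, accB2);
      tune(scPhi, accPhi); tune(scSwap, accSwap); tune(scLvl, accLvl);
      tune(scSS, accSS); tune(scHS, accHS);
    }
    if (t == nBurnin) {           // reset counters for post-burn-in rates
      accS.zeros(); accH.zeros(); accB1.zeros(); accB2.zeros(); accPhi.zeros();
      accSwap.zeros(); accLvl.zeros(); accSS.zeros(); accHS.zeros();
    }
    if (t > nBurnin) postSweeps += 1.0;

    // ---- record ----
    if (t > nBurnin && (t - nBurnin) % thin == 0 && keep < nKeep) {
      int col = 0;
      for (int j = 0; j < J; ++j) samples(keep, col++) = b1[j];
      for (int j = 0; j < J; ++j) samples(keep, col++) = b2[j];
      for (int j = 0; j < J; ++j) samples(keep, col++) = sigS[j];
      for (int j = 0; j < J; ++j) samples(keep, col++) = sigH[j];
      if (variant == 2) {
        samples(keep, col++) = alpha; samples(keep, col++) = beta;
        samples(keep, col++) = sigB1; samples(keep, col++) = sigB2;
      } else if (variant == 3) {
        samples(keep, col++) = alpha; samples(keep, col++) = beta;
        samples(keep, col++) = sig1; samples(keep, col++) = phi1;
        samples(keep, col++) = sig2; samples(keep, col++) = phi2;
      }
      if (useLik) {
        double dev = 0.0;
        for (int i = 0; i < N; ++i)
          dev += O[i] * (logE[i] + eta[i]) - E[i] * std::exp(eta[i]);
        devOut[keep] = -2.0 * dev + 2.0 * devConst;
      } else devOut[keep] = NA_REAL;
      logThetaSum += eta;
      keep++;
    }
  }

  if (postSweeps > 0) {
    postAccS = arma::accu(accS) / (postSweeps * N);
    postAccH = arma::accu(accH) / (postSweeps * N);
    postAccB1 = arma::accu(accB1) / (postSweeps * J);
    postAccB2 = arma::accu(accB2) / (postSweeps * J);
    postAccPhi = arma::accu(accPhi) / (postSweeps * 2.0);
  }

  List finalState = List::create(
    _["b1"] = NumericVector(b1.begin(), b1.end()),
    _["b2"] = NumericVector(b2.begin(), b2.end()),
    _["S"] = NumericVector(S.begin(), S.end()),
    _["H"] = NumericVector(H.begin(), H.end()),
    _["sigmaS"] = NumericVector(sigS.begin(), sigS.end()),
    _["sigmaH"] = NumericVector(sigH.begin(), sigH.end()),
    _["alpha"] = alpha, _["beta"] = beta,
    _["sigmaB1"] = sigB1, _["sigmaB2"] = sigB2,
    _["sigma1"] = sig1, _["phi1"] = phi1,
    _["sigma2"] = sig2, _["phi2"] = phi2);
  List scalesOut = List::create(
    _["S"] = NumericVector(scS.begin(), scS.end()),
    _["H"] = NumericVector(scH.begin(), scH.end()),
    _["b1"] = NumericVector(scB1.begin(), scB1.end()),
    _["b2"] = NumericVector(scB2.begin(), scB2.end()),
    _["phi"] = NumericVector(scPhi.begin(), scPhi.end()),
    _["swap"] = NumericVector(scSwap.begin(), scSwap.end()),
    _["level"] = NumericVector(scLvl.begin(), scLvl.end()),
    _["sScale"] = NumericVector(scSS.begin(), scSS.end()),
    _["hScale"] = NumericVector(scHS.begin(), scHS.end()));
  return List::create(_["samples"] = samples, _["deviance"] = devOut,
                      _["logThetaSum"] = logThetaSum, _["nKeep"] = keep,
                      _["finalState"] = finalState, _["scales"] = scalesOut,
                      _["accept"] = List::create(
                        _["S"] = postAccS, _["H"] = postAccH,
                        _["b1"] = postAccB1, _["b2"] = postAccB2,
                        _["phi"] = postAccPhi));
}
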