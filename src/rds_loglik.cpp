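// Marginal log-likelihood of the joint rate-duration-severity model.
//
// Per subject the conditional (on the trivariate random effect z) log
// likelihood is a sum of AFT density/survival terms for between- and
// within-exacerbation gap times plus Bernoulli-logit terms for severity;
// the marginal likelihood integrates exp(conditional) against the MVN
// random-effect law by (adaptive) tensor Gauss-Hermite quadrature, with the
// zero-inflation mixture applied outside the integral.  Subjects without
// events involve only the rate random effect, so their integral collapses
// to one dimension.
//
// The integral is computed in whitened coordinates z = L v with
// L = chol(Sigma_Z) and v ~ N(0, I): no precision matrix is ever formed,
// so the computation stays accurate when the optimizer visits
// near-singular covariances (correlations close to +-1 or tiny SDs).
// The conditional log-likelihood is concave in z for every supported
// family (all second derivatives of the per-term contributions are
// negative), hence the negative Hessian of the whitened log posterior,
// I - L^T diag(h) L with h <= 0, is always positive definite and the
// Newton mode search is globally convergent with step halving.
//
// Episode data arrive flattened across subjects (offsets derived from the
// per-subject episode counts); the linear predictors at z = 0 are computed
// in R by one matrix product per submodel.  Standardized residuals
// u0 = (log t - eta)/sigma and the z-free Jacobian constants are
// precomputed per subject so the inner tensor-grid loop touches no log().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int FAM_WEIB = 0;   // extreme-value residual (Weibull / exponential)
static const int FAM_LNORM = 1;  // normal residual
static const int FAM_LLOGIS = 2; // logistic residual

static const double LOG_SQRT_2PI = 0.9189385332046727;
static const double LOG_2PI = 1.8378770664093453;
static const double LOG_2 = 0.6931471805599453;
static const double SQRT2 = 1.4142135623730951;

inline double log_plogis(double lp) {
  // log(1/(1+exp(-lp))), overflow safe
  return lp < 0 ? lp - log1p(std::exp(lp)) : -log1p(std::exp(-lp));
}

// value/gradient/curvature of a log-density or log-survival term with
// respect to the standardized residual u = (log t - eta)/sigma
// (the z-free -log(sigma t) Jacobian of density terms is kept separately)
struct D3 { double v, g, h; };

inline D3 logdens_u(double u, int fam) {
  D3 d;
  switch (fam) {
  case FAM_LNORM:
    d.v = -0.5 * u * u - LOG_SQRT_2PI;
    d.g = -u;
    d.h = -1.0;
    break;
  case FAM_LLOGIS: {
    double p = 1.0 / (1.0 + std::exp(-u));
    d.v = u - 2.0 * (u < 0 ? log1p(std::exp(u)) : u + log1p(std::exp(-u)));
    d.g = 1.0 - 2.0 * p;
    d.h = -2.0 * p * (1.0 - p);
    break;
  }
  default: { // extreme value
    double eu = std::exp(u);
    d.v = u - eu;
    d.g = 1.0 - eu;
    d.h = -eu;
  }
  }
  return d;
}

inline D3 logsurv_u(double u, int fam) {
  D3 d;
  switch (fam) {
  case FAM_LNORM: {
    d.v = R::pnorm(u, 0.0, 1.0, 0, 1); // log(1 - Phi(u))
    double r = std::exp(R::dnorm(u, 0.0, 1.0, 1) - d.v); // inverse Mills ratio
    d.g = -r;
    d.h = -r * (r - u);
    break;
  }
  case FAM_LLOGIS: {
    double p = 1.0 / (1.0 + std::exp(-u));
    d.v = (u < 0) ? -log1p(std::exp(u)) : -(u + log1p(std::exp(-u)));
    d.g = -p;
    d.h = -p * (1.0 - p);
    break;
  }
  default: {
    double eu = std::exp(u);
    d.v = -eu;
    d.g = -eu;
    d.h = -eu;
  }
  }
  return d;
}

struct Pars {
  double sigB, sigW;
  int famB, famW;
  bool hasW, hasS;
  int d;                  // number of active random effects
  int idxB, idxW, idxS;   // position of each component among active (-1 if none)
  std::vector<double> Lsig;     // lower Cholesky of Sigma, d*d row-major
  double sdBmarg;               // sqrt(Sigma[B,B]) (marginal law for M = 0)
};

// per-subject precomputed view: standardized residuals at z = 0 and the
// z-free Jacobian constant of the density terms
struct SubjView {
  int m;
  const double *uB0;   // (log B_j - etaB0_j)/sigB, length m
  const double *uW0;   // (log W_j - etaW0_j)/sigW, length m (or null)
  const int *S, *WC;   // severity, within-censored flags (or null)
  const double *lpS0;  // severity linear predictors, length m (or null)
  double uC0;          // final-gap residual (log fgap - etaB0_m)/sigB
  bool hasC;           // censored final gap with positive length
  double jac;          // -sum log(sigB B_j) - sum_{uncens} log(sigW W_j)
  // effective random-effect layout for this evaluation
  int d, idxB, idxW, idxS;
  const double *L;     // d*d lower Cholesky factor in effect
};

// conditional log-likelihood at z (gradient / diagonal Hessian in z if
// requested; each term depends on exactly one component of z)
static double cond_ll(const SubjView& s, const Pars& p, const double* z,
                      double* gz, double* hz) {
  double zBs = s.idxB >= 0 ? z[s.idxB] / p.sigB : 0.0;
  double zWs = s.idxW >= 0 ? z[s.idxW] / p.sigW : 0.0;
  double zS = s.idxS >= 0 ? z[s.idxS] : 0.0;
  double ll = s.jac;
  double gB = 0.0, gW = 0.0, gS = 0.0, hB = 0.0, hW = 0.0, hS = 0.0;
  for (int j = 0; j < s.m; ++j) {
    D3 dB = logdens_u(s.uB0[j] - zBs, p.famB);
    ll += dB.v;
    gB += dB.g;
    hB += dB.h;
    if (p.hasW) {
      double uW = s.uW0[j] - zWs;
      D3 dW = s.WC[j] ? logsurv_u(uW, p.famW) : logdens_u(uW, p.famW);
      ll += dW.v;
      gW += dW.g;
      hW += dW.h;
    }
    if (p.hasS) {
      double lp = s.lpS0[j] + zS;
      double pr = 1.0 / (1.0 + std::exp(-lp));
      ll += s.S[j] ? log_plogis(lp) : log_plogis(-lp);
      gS += s.S[j] - pr;
      hS += -pr * (1.0 - pr);
    }
  }
  if (s.hasC) {
    D3 dC = logsurv_u(s.uC0 - zBs, p.famB);
    ll += dC.v;
    gB += dC.g;
    hB += dC.h;
  }
  if (gz) {
    for (int k = 0; k < s.d; ++k) { gz[k] = 0.0; hz[k] = 0.0; }
    // chain rule: du/dz = -1/sigma
    if (s.idxB >= 0) {
      gz[s.idxB] = -gB / p.sigB;
      hz[s.idxB] = hB / (p.sigB * p.sigB);
    }
    if (s.idxW >= 0) {
      gz[s.idxW] = -gW / p.sigW;
      hz[s.idxW] = hW / (p.sigW * p.sigW);
    }
    if (s.idxS >= 0) { gz[s.idxS] = gS; hz[s.idxS] = hS; }
  }
  return ll;
}

// whitened log posterior G(v) = cond(Lv) + log phi_I(v); optional gradient
// and negative Hessian in v: grad = L^T gz - v, negH = I - L^T diag(hz) L
static double G_white(const SubjView& s, const Pars& p, const double* v,
                      double* gradv, double* negHv) {
  int d = s.d;
  double z[3], gz[3], hz[3];
  for (int i = 0; i < d; ++i) {
    double zi = 0.0;
    for (int j = 0; j <= i; ++j) zi += s.L[i * d + j] * v[j];
    z[i] = zi;
  }
  double c = cond_ll(s, p, z, gradv ? gz : nullptr, gradv ? hz : nullptr);
  double vv = 0.0;
  for (int i = 0; i < d; ++i) vv += v[i] * v[i];
  double val = c - 0.5 * d * LOG_2PI - 0.5 * vv;
  if (gradv) {
    for (int j = 0; j < d; ++j) {
      double gj = -v[j];
      for (int i = j; i < d; ++i) gj += s.L[i * d + j] * gz[i];
      gradv[j] = gj;
    }
    for (int j = 0; j < d; ++j) {
      for (int k = 0; k <= j; ++k) {
        double hjk = (j == k) ? 1.0 : 0.0;
        for (int i = std::max(j, k); i < d; ++i) {
          hjk -= s.L[i * d + j] * hz[i] * s.L[i * d + k];
        }
        negHv[j * d + k] = negHv[k * d + j] = hjk;
      }
    }
  }
  return val;
}

// Cholesky (lower) of a small SPD matrix, row-major; false if not PD
static bool chol_small(const double* a, double* L, int d) {
  for (int i = 0; i < d * d; ++i) L[i] = 0.0;
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double sum = a[i * d + j];
      for (int k = 0; k < j; ++k) sum -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (sum <= 0.0) return false;
        L[i * d + i] = std::sqrt(sum);
      } else {
        L[i * d + j] = sum / L[j * d + j];
      }
    }
  }
  return true;
}

// Newton search for the mode of the whitened log posterior G(v).
// On exit v holds the mode and negH the negative Hessian of G there.
static void posterior_mode(const SubjView& s, const Pars& p,
                           double* v, double* negH,
                           int maxit = 50, double tol = 1e-9) {
  int d = s.d;
  std::vector<double> g(d), step(d), L(d * d), vn(d), y(d);
  std::vector<double> gn(d), negHn(d * d);
  double G = G_white(s, p, v, g.data(), negH);
  for (int it = 0; it < maxit; ++it) {
    double gnorm = 0.0;
    for (int i = 0; i < d; ++i) gnorm = std::max(gnorm, std::fabs(g[i]));
    if (gnorm < tol) return;
    if (!chol_small(negH, L.data(), d)) return; // cannot happen for h <= 0
    // solve negH * step = g via the Cholesky factor
    for (int i = 0; i < d; ++i) {
      double sum = g[i];
      for (int k = 0; k < i; ++k) sum -= L[i * d + k] * y[k];
      y[i] = sum / L[i * d + i];
    }
    for (int i = d - 1; i >= 0; --i) {
      double sum = y[i];
      for (int k = i + 1; k < d; ++k) sum -= L[k * d + i] * step[k];
      step[i] = sum / L[i * d + i];
    }
    double alpha = 1.0;
    bool accepted = false;
    for (int half = 0; half < 30; ++half) {
      for (int i = 0; i < d; ++i) vn[i] = v[i] + alpha * step[i];
      double Gn = G_white(s, p, vn.data(), gn.data(), negHn.data());
      if (Gn >= G - 1e-12) { G = Gn; accepted = true; break; }
      alpha *= 0.5;
    }
    if (!accepted) break; // cannot improve further: treat v as the mode
    for (int i = 0; i < d; ++i) v[i] = vn[i];
    g = gn;
    for (int i = 0; i < d * d; ++i) negH[i] = negHn[i];
  }
}

// log E_Z[exp(cond_ll)] = log integral of exp(G(v)) dv by tensor
// Gauss-Hermite quadrature around center vhat with factor A:
//   log E = LSE_k [ d/2 log 2 + log|det A| + sum_i log w_i + |x_k|^2
//                   + G(v_k) ]  with v_k = vhat + sqrt2 A x_k
static double gh_marginal(const SubjView& s, const Pars& p,
                          const double* vhat, const double* A, double logdetA,
                          const NumericVector& ghx,
                          const std::vector<double>& loggw) {
  int d = s.d;
  int n = ghx.size();
  int K = 1;
  for (int i = 0; i < d; ++i) K *= n;
  std::vector<int> idx(d, 0);
  std::vector<double> v(d), x(d), terms(K);
  double base = 0.5 * d * LOG_2 + logdetA;
  double mx = R_NegInf;
  for (int k = 0; k < K; ++k) {
    double lw = base, xx = 0.0;
    for (int i = 0; i < d; ++i) {
      x[i] = ghx[idx[i]];
      lw += loggw[idx[i]];
      xx += x[i] * x[i];
    }
    for (int i = 0; i < d; ++i) {
      double vi = vhat[i];
      for (int j = 0; j < d; ++j) vi += SQRT2 * A[i * d + j] * x[j];
      v[i] = vi;
    }
    double t = lw + xx + G_white(s, p, v.data(), nullptr, nullptr);
    terms[k] = t;
    if (t > mx) mx = t;
    for (int i = 0; i < d; ++i) { // advance tensor index
      if (++idx[i] < n) break;
      idx[i] = 0;
    }
  }
  if (!R_finite(mx)) return mx;
  double acc = 0.0;
  for (int k = 0; k < K; ++k) acc += std::exp(terms[k] - mx);
  return mx + std::log(acc);
}

// invert a lower-triangular factor
static void inv_lower(const double* L, double* A, int d) {
  for (int i = 0; i < d * d; ++i) A[i] = 0.0;
  for (int j = 0; j < d; ++j) {
    A[j * d + j] = 1.0 / L[j * d + j];
    for (int i = j + 1; i < d; ++i) {
      double sum = 0.0;
      for (int k = j; k < i; ++k) sum += L[i * d + k] * A[k * d + j];
      A[i * d + j] = -sum / L[i * d + i];
    }
  }
}

// [[Rcpp::export]]
List rds_marginal_loglik_cpp(List dat, List par,
                             NumericVector ghx, NumericVector ghw,
                             bool adaptive,
                             Nullable<NumericMatrix> vmodeStart,
                             bool wantModes) {
  int n = as<int>(dat["n"]);
  IntegerVector m = dat["m"];
  NumericVector logBall = dat["logB"], logWall = dat["logW"];
  IntegerVector Sall = dat["S"], WCall = dat["WC"];
  NumericVector logfgap = dat["logfgap"];
  IntegerVector fgap_cens = dat["fgap_cens"];
  NumericVector etaB0 = dat["etaB0"], etaW0 = dat["etaW0"], lpS0 = dat["lpS0"];
  NumericVector log_pi = dat["log_pi"], log_1mpi = dat["log_1mpi"];
  bool has_zi = as<bool>(dat["has_zi"]);

  Pars p;
  p.sigB = as<double>(par["sigB"]);
  p.famB = as<int>(par["famB"]);
  p.hasW = as<bool>(par["hasW"]);
  p.sigW = p.hasW ? as<double>(par["sigW"]) : 1.0;
  p.famW = p.hasW ? as<int>(par["famW"]) : 0;
  p.hasS = as<bool>(par["hasS"]);
  p.d = as<int>(par["d"]);
  IntegerVector reIdx = par["reIdx"]; // position of B, W, S among active (-1)
  p.idxB = reIdx[0]; p.idxW = reIdx[1]; p.idxS = reIdx[2];
  int d = p.d;
  if (d > 0) {
    NumericMatrix LS = par["cholSig"];
    p.Lsig.assign(d * d, 0.0);
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j)
        p.Lsig[i * d + j] = LS(i, j);
    p.sdBmarg = as<double>(par["sdBmarg"]);
  } else {
    p.sdBmarg = 0.0;
  }
  double L1 = p.sdBmarg; // 1-D factor for subjects without episodes

  int nq = ghx.size();
  std::vector<double> loggw(nq);
  for (int i = 0; i < nq; ++i) loggw[i] = std::log(ghw[i]);

  NumericVector out(n);
  NumericMatrix modes(wantModes ? n : 0, wantModes ? 3 : 0);
  NumericMatrix vmodes(wantModes ? n : 0, wantModes ? 3 : 0);
  NumericMatrix mstart;
  bool hasStart = vmodeStart.isNotNull();
  if (hasStart) mstart = NumericMatrix(vmodeStart);

  double log_sigB = std::log(p.sigB), log_sigW = std::log(p.sigW);
  int mmax = 0;
  for (int i = 0; i < n; ++i) if (m[i] > mmax) mmax = m[i];
  std::vector<double> uB0(mmax + 1), uW0(mmax + 1);
  std::vector<double> vhat(3), negH(9), L(9), A(9);
  R_xlen_t epoff = 0, rateoff = 0;

  for (int i = 0; i < n; ++i) {
    SubjView s;
    s.m = m[i];
    s.S = Sall.size() ? INTEGER(Sall) + epoff : nullptr;
    s.WC = WCall.size() ? INTEGER(WCall) + epoff : nullptr;
    s.lpS0 = lpS0.size() ? REAL(lpS0) + epoff : nullptr;
    // precompute standardized residuals and Jacobian constants
    double jac = 0.0;
    for (int j = 0; j < s.m; ++j) {
      double lB = logBall[epoff + j];
      uB0[j] = (lB - etaB0[rateoff + j]) / p.sigB;
      jac -= log_sigB + lB;
      if (p.hasW) {
        double lW = logWall[epoff + j];
        uW0[j] = (lW - etaW0[epoff + j]) / p.sigW;
        if (!s.WC[j]) jac -= log_sigW + lW;
      }
    }
    s.uB0 = uB0.data();
    s.uW0 = p.hasW ? uW0.data() : nullptr;
    s.jac = jac;
    s.hasC = fgap_cens[i] == 1 && R_finite(logfgap[i]);
    s.uC0 = s.hasC ? (logfgap[i] - etaB0[rateoff + s.m]) / p.sigB : 0.0;
    epoff += s.m;
    rateoff += s.m + 1;

    double logE;
    if (wantModes) {
      modes(i, 0) = modes(i, 1) = modes(i, 2) = NA_REAL;
      vmodes(i, 0) = vmodes(i, 1) = vmodes(i, 2) = 0.0;
    }
    if ((s.m == 0 && p.idxB < 0) || d == 0) {
      // no relevant random effect: the conditional value at z = 0 is exact
      s.d = 0; s.idxB = s.idxW = s.idxS = -1; s.L = nullptr;
      double z0[3] = {0.0, 0.0, 0.0};
      logE = cond_ll(s, p, z0, nullptr, nullptr);
      if (wantModes) { modes(i, 0) = modes(i, 1) = modes(i, 2) = 0.0; }
    } else if (s.m == 0) {
      // only z_B enters: exact collapse to its 1-D marginal N(0, sd_B^2)
      s.d = 1; s.idxB = 0; s.idxW = -1; s.idxS = -1; s.L = &L1;
      double v1 = hasStart && R_finite(mstart(i, 0)) ? mstart(i, 0) : 0.0;
      double a1 = 1.0, logdetA = 0.0, nh = 1.0;
      if (adaptive) {
        posterior_mode(s, p, &v1, &nh);
        a1 = 1.0 / std::sqrt(nh);
        logdetA = std::log(a1);
      } else {
        v1 = 0.0;
      }
      logE = gh_marginal(s, p, &v1, &a1, logdetA, ghx, loggw);
      if (wantModes) {
        double vm = v1;
        if (!adaptive) { vm = 0.0; posterior_mode(s, p, &vm, &nh); }
        modes(i, 0) = L1 * vm;
        vmodes(i, 0) = vm;
      }
    } else {
      s.d = d; s.idxB = p.idxB; s.idxW = p.idxW; s.idxS = p.idxS;
      s.L = p.Lsig.data();
      for (int k = 0; k < d; ++k) {
        vhat[k] = hasStart && R_finite(mstart(i, k)) ? mstart(i, k) : 0.0;
      }
      double logdetA = 0.0;
      if (adaptive) {
        posterior_mode(s, p, vhat.data(), negH.data());
        // negH = I - L^T diag(h) L is PD by construction
        if (chol_small(negH.data(), L.data(), d)) {
          inv_lower(L.data(), A.data(), d);
          for (int k = 0; k < d; ++k) logdetA -= std::log(L[k * d + k]);
        } else { // numerically degenerate: fall back to the prior grid
          for (int k = 0; k < d; ++k) vhat[k] = 0.0;
          for (int k = 0; k < d * d; ++k) A[k] = (k % (d + 1)) == 0 ? 1.0 : 0.0;
          logdetA = 0.0;
        }
      } else {
        for (int k = 0; k < d; ++k) vhat[k] = 0.0;
        for (int k = 0; k < d * d; ++k) A[k] = (k % (d + 1)) == 0 ? 1.0 : 0.0;
      }
      logE = gh_marginal(s, p, vhat.data(), A.data(), logdetA, ghx, loggw);
      if (wantModes) {
        std::vector<double> vm(vhat.begin(), vhat.end());
        if (!adaptive) {
          for (int k = 0; k < d; ++k) vm[k] = 0.0;
          posterior_mode(s, p, vm.data(), negH.data());
        }
        double zm[3];
        for (int a = 0; a < d; ++a) {
          double za = 0.0;
          for (int b = 0; b <= a; ++b) za += p.Lsig[a * d + b] * vm[b];
          zm[a] = za;
          vmodes(i, a) = vm[a];
        }
        if (p.idxB >= 0) modes(i, 0) = zm[p.idxB];
        if (p.idxW >= 0) modes(i, 1) = zm[p.idxW];
        if (p.idxS >= 0) modes(i, 2) = zm[p.idxS];
      }
    }

    double ll;
    if (has_zi) {
      if (s.m == 0) {
        double a = log_pi[i], b = log_1mpi[i] + logE;
        double mx = std::max(a, b);
        ll = mx + std::log(std::exp(a - mx) + std::exp(b - mx));
      } else {
        ll = log_1mpi[i] + logE;
      }
    } else {
      ll = logE;
    }
    if (!R_finite(ll)) {
      stop("marginal likelihood is non-finite for subject index %d", i + 1);
    }
    out[i] = ll;
  }

  double total = sum(out);
  List res = List::create(_["per_subject"] = out,
                          _["total"] = total);
  if (wantModes) {
    res["modes"] = modes;
    res["vmodes"] = vmodes;
  }
  return res;
}
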