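// Adaptive Metropolis-within-Gibbs sampler and model log-posteriors.
//
// All four hierarchical models share the same machinery: a parameter vector on
// an unconstrained scale (scale parameters sampled as logs with Jacobian
// corrections, correlations as tanh of unconstrained reals, group deviations
// non-centered), a separable log-prior (one term per parameter), and a
// per-observation log-likelihood.  The sampler updates one coordinate at a
// time with a Gaussian random-walk proposal whose scale is tuned towards a
// 0.44 acceptance rate during warmup; only the observations a coordinate can
// touch are re-evaluated, which keeps a full sweep cheap even with hundreds of
// group-level coordinates.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// density helpers

// Student-t lpdf with location/scale; lgamma constants cached on nu.
struct TCache {
  double nu = -1.0, lconst = 0.0;
  inline double lpdf(double x, double nu_, double mu, double sigma) {
    if (nu_ != nu) {
      nu = nu_;
      lconst = R::lgammafn(0.5 * (nu + 1.0)) - R::lgammafn(0.5 * nu) -
               0.5 * std::log(nu * M_PI);
    }
    double r = (x - mu) / sigma;
    return lconst - std::log(sigma) - 0.5 * (nu + 1.0) * std::log1p(r * r / nu);
  }
};

// half-Student-t(3, 0, scale) prior on sigma = exp(lx), including Jacobian
static inline double half_t3_lp(double lx, double scale) {
  double s = std::exp(lx);
  if (!std::isfinite(s)) return R_NegInf;
  double r = s / scale;
  // log(2) + t3 lpdf + Jacobian lx
  return M_LN2 + R::lgammafn(2.0) - R::lgammafn(1.5) - 0.5 * std::log(3.0 * M_PI) -
         std::log(scale) - 2.0 * std::log1p(r * r / 3.0) + lx;
}

// Gamma(shape 2, rate 0.1) prior on nu = exp(lx), including Jacobian
static inline double gamma_nu_lp(double lx) {
  double v = std::exp(lx);
  if (!std::isfinite(v)) return R_NegInf;
  return R::dgamma(v, 2.0, 10.0, 1) + lx;
}

static inline double std_normal_lp(double z) {
  return -0.5 * z * z - 0.918938533204672742; // -log(sqrt(2*pi))
}

// Lower-triangular Cholesky factor of a correlation matrix from canonical
// partial correlations z in (-1,1), packed row-wise (i > j).
static void cpc_chol(const double* z, int r, double* L) {
  int idx = 0;
  for (int i = 0; i < r; ++i) {
    double sq = 0.0;
    for (int j = 0; j < i; ++j) {
      double l = z[idx++] * std::sqrt(1.0 - sq);
      L[i * r + j] = l;
      sq += l * l;
    }
    L[i * r + i] = std::sqrt(std::max(0.0, 1.0 - sq));
    for (int j = i + 1; j < r; ++j) L[i * r + j] = 0.0;
  }
}

// ---------------------------------------------------------------------------
// model interface

struct Model {
  int n = 0;
  int d = 0;
  std::vector<std::vector<int> > affected; // per parameter; empty => all obs
  virtual double loglik_i(int i, const double* th) = 0;
  virtual double logprior_p(int p, double v) const = 0;
  virtual ~Model() {}
  double logprior(const double* th) const {
    double lp = 0.0;
    for (int p = 0; p < d; ++p) {
      lp += logprior_p(p, th[p]);
      if (!std::isfinite(lp)) return R_NegInf;
    }
    return lp;
  }
};

// ---------------------------------------------------------------------------
// von Bertalanffy growth: y = log length, mean = log(Linf*(1-exp(-K(t-t0))))

struct VbgeModel : Model {
  std::vector<double> y, t;
  std::vector<int> area, coh;
  int ncoh, nL, nK, nT;
  int iL, iK, iT, isL, isK, inu, isg, izL, izK;
  TCache tc;

  VbgeModel(List data) {
    y = as<std::vector<double> >(data["y"]);
    t = as<std::vector<double> >(data["t"]);
    area = as<std::vector<int> >(data["area"]);
    coh = as<std::vector<int> >(data["coh"]);
    ncoh = as<int>(data["ncoh"]);
    nL = as<bool>(data["area_Linf"]) ? 2 : 1;
    nK = as<bool>(data["area_K"]) ? 2 : 1;
    nT = as<bool>(data["area_t0"]) ? 2 : 1;
    n = (int)y.size();
    iL = 0; iK = iL + nL; iT = iK + nK; isL = iT + nT; isK = isL + nL;
    inu = isK + nK; isg = inu + 1; izL = isg + 1; izK = izL + nL * ncoh;
    d = izK + nK * ncoh;
    affected.assign(d, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      int aL = nL == 2 ? area[i] : 0, aK = nK == 2 ? area[i] : 0;
      affected[izL + aL * ncoh + coh[i]].push_back(i);
      affected[izK + aK * ncoh + coh[i]].push_back(i);
      // area-specific globals only touch their own area's observations
      if (nL == 2) {
        affected[iL + area[i]].push_back(i);
        affected[isL + area[i]].push_back(i);
      }
      if (nK == 2) {
        affected[iK + area[i]].push_back(i);
        affected[isK + area[i]].push_back(i);
      }
      if (nT == 2) affected[iT + area[i]].push_back(i);
    }
    // an area with no observations leaves its sets empty, which safely falls
    // back to a full pass
  }

  double loglik_i(int i, const double* th) {
    int a = area[i], j = coh[i];
    int aL = nL == 2 ? a : 0, aK = nK == 2 ? a : 0, aT = nT == 2 ? a : 0;
    double Linf = std::exp(th[iL + aL]) + std::exp(th[isL + aL]) * th[izL + aL * ncoh + j];
    double K = std::exp(th[iK + aK]) + std::exp(th[isK + aK]) * th[izK + aK * ncoh + j];
    if (Linf <= 0.0 || K <= 0.0) return R_NegInf;
    double g = -std::expm1(-K * (t[i] - th[iT + aT]));
    if (g <= 0.0) return R_NegInf;
    return tc.lpdf(y[i], std::exp(th[inu]), std::log(Linf) + std::log(g),
                   std::exp(th[isg]));
  }

  double logprior_p(int p, double v) const {
    if (p >= izK) return std_normal_lp(v);
    if (p >= izL) return std_normal_lp(v);
    if (p == isg) return half_t3_lp(v, 2.5);
    if (p == inu) return gamma_nu_lp(v);
    if (p >= isL) return half_t3_lp(v, 2.5);          // sigma_Linf / sigma_K
    if (p >= iT) return R::dnorm(v, -0.5, 1.0, 1);    // t0, natural scale
    if (p >= iK) return R::dnorm(std::exp(v), 0.2, 0.1, 1) + v;  // mu_K
    return R::dnorm(std::exp(v), 45.0, 20.0, 1) + v;  // mu_Linf
  }
};

// ---------------------------------------------------------------------------
// allometric specific growth: G = alpha_{area,cohort,individual} * L^theta

struct AlloModel : Model {
  std::vector<double> y, lL;
  std::vector<int> area, gcoh, gid;
  int Gc, Gi, nT;
  int iA, iT, isC, isI, inu, isg, izC, izI;
  TCache tc;

  AlloModel(List data) {
    y = as<std::vector<double> >(data["y"]);
    lL = as<std::vector<double> >(data["lL"]);
    area = as<std::vector<int> >(data["area"]);
    gcoh = as<std::vector<int> >(data["gcoh"]);
    gid = as<std::vector<int> >(data["gid"]);
    Gc = as<int>(data["Gc"]);
    Gi = as<int>(data["Gi"]);
    nT = as<bool>(data["area_theta"]) ? 2 : 1;
    n = (int)y.size();
    iA = 0; iT = 2; isC = iT + nT; isI = isC + 1; inu = isI + 1; isg = inu + 1;
    izC = isg + 1; izI = izC + Gc;
    d = izI + Gi;
    affected.assign(d, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      affected[izC + gcoh[i]].push_back(i);
      affected[izI + gid[i]].push_back(i);
    }
  }

  double loglik_i(int i, const double* th) {
    int a = area[i];
    double alpha = th[iA + a] + std::exp(th[isC]) * th[izC + gcoh[i]] +
                   std::exp(th[isI]) * th[izI + gid[i]];
    double mu = alpha * std::exp(th[iT + (nT == 2 ? a : 0)] * lL[i]);
    return tc.lpdf(y[i], std::exp(th[inu]), mu, std::exp(th[isg]));
  }

  double logprior_p(int p, double v) const {
    if (p >= izC) return std_normal_lp(v);
    if (p == isg) return half_t3_lp(v, 13.3);
    if (p == inu) return gamma_nu_lp(v);
    if (p == isI || p == isC) return half_t3_lp(v, 13.3);
    if (p >= iT) return R::dnorm(v, -1.2, 0.3, 1);     // theta
    return R::dnorm(v, 500.0, 100.0, 1);               // mu_alpha
  }
};

// ---------------------------------------------------------------------------
// catch curve: log CPUE ~ t(nu, b0*heat + b1*ref + b2*age + b3*age*heat + RE)
// RE: a subset of the design columns varies by cohort under a correlated MVN
// (non-centered: u_j = diag(tau) %*% Lcorr %*% z_j).

struct CcModel : Model {
  std::vector<double> y, age;
  std::vector<int> heat, coh;
  int J, nb, r, ncor;
  std::vector<int> cols; // active fixed-effect design columns
  std::vector<int> re;   // design-column indices with cohort-varying deviations
  int ib, itau, icor, inu, isg, iz;
  TCache tc;

  CcModel(List data) {
    y = as<std::vector<double> >(data["y"]);
    age = as<std::vector<double> >(data["age"]);
    heat = as<std::vector<int> >(data["heat"]);
    coh = as<std::vector<int> >(data["coh"]);
    J = as<int>(data["J"]);
    cols = as<std::vector<int> >(data["cols"]); // active design columns
    nb = (int)cols.size();
    re = as<std::vector<int> >(data["re"]);
    r = (int)re.size();
    ncor = r * (r - 1) / 2;
    n = (int)y.size();
    ib = 0; itau = nb; icor = itau + r; inu = icor + ncor; isg = inu + 1;
    iz = isg + 1;
    d = iz + J * r;
    affected.assign(d, std::vector<int>());
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < r; ++c) affected[iz + coh[i] * r + c].push_back(i);
  }

  inline double xval(int i, int c) const {
    switch (c) {
      case 0: return (double)heat[i];
      case 1: return 1.0 - heat[i];
      case 2: return age[i];
      default: return age[i] * heat[i];
    }
  }

  double loglik_i(int i, const double* th) {
    double mu = 0.0;
    for (int c = 0; c < nb; ++c) mu += th[ib + c] * xval(i, cols[c]);
    if (r > 0) {
      double zt[6], Lc[16], u;
      for (int k = 0; k < ncor; ++k) zt[k] = std::tanh(th[icor + k]);
      cpc_chol(zt, r, Lc);
      const double* zj = th + iz + coh[i] * r;
      for (int c = 0; c < r; ++c) {
        u = 0.0;
        for (int k = 0; k <= c; ++k) u += Lc[c * r + k] * zj[k];
        mu += std::exp(th[itau + c]) * u * xval(i, re[c]);
      }
    }
    return tc.lpdf(y[i], std::exp(th[inu]), mu, std::exp(th[isg]));
  }

  double logprior_p(int p, double v) const {
    if (p >= iz) return std_normal_lp(v);
    if (p == isg) return half_t3_lp(v, 2.5);
    if (p == inu) return gamma_nu_lp(v);
    if (p >= icor) { // uniform partial correlation via tanh, with Jacobian
      double z = std::tanh(v);
      return std::log1p(-z * z) - M_LN2;
    }
    if (p >= itau) return half_t3_lp(v, 2.5);
    return 0.0; // flat prior on regression coefficients
  }
};

// ---------------------------------------------------------------------------
// lognormal mean size/age: log y ~ N(b_heat*heat + b_ref*ref + u_{year}, sigma)
// with frequency weights; year deviations either per-area (r=2, correlated)
// or common (r=1).

struct LnormModel : Model {
  std::vector<double> ly, w;
  std::vector<int> heat, yr;
  int J, r;
  int ib, itau, icor, isg, iz;

  LnormModel(List data) {
    ly = as<std::vector<double> >(data["ly"]);
    w = as<std::vector<double> >(data["w"]);
    heat = as<std::vector<int> >(data["heat"]);
    yr = as<std::vector<int> >(data["yr"]);
    J = as<int>(data["J"]);
    r = as<int>(data["r"]); // 2 = per-area year intercepts, 1 = common
    n = (int)ly.size();
    ib = 0; itau = 2; icor = itau + r; isg = icor + (r == 2 ? 1 : 0);
    iz = isg + 1;
    d = iz + J * r;
    affected.assign(d, std::vector<int>());
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < r; ++c) affected[iz + yr[i] * r + c].push_back(i);
  }

  double loglik_i(int i, const double* th) {
    double mu = th[ib + (heat[i] ? 0 : 1)];
    const double* zj = th + iz + yr[i] * r;
    if (r == 2) {
      double rho = std::tanh(th[icor]);
      double u0 = zj[0], u1 = rho * zj[0] + std::sqrt(1.0 - rho * rho) * zj[1];
      mu += std::exp(th[itau + (heat[i] ? 0 : 1)]) * (heat[i] ? u0 : u1);
    } else {
      mu += std::exp(th[itau]) * zj[0];
    }
    double sg = std::exp(th[isg]);
    // lognormal lpdf of y = dnorm(log y | mu, sigma) - log y
    return w[i] * (R::dnorm(ly[i], mu, sg, 1) - ly[i]);
  }

  double logprior_p(int p, double v) const {
    if (p >= iz) return std_normal_lp(v);
    if (p == isg) return half_t3_lp(v, 2.5);
    if (r == 2 && p == icor) {
      double z = std::tanh(v);
      return std::log1p(-z * z) - M_LN2;
    }
    if (p >= itau && p < itau + r) return half_t3_lp(v, 2.5);
    if (p < 2) return 0.0; // flat intercepts
    return 0.0;            // unused slot (r==1 leaves itau+1 absent by layout)
  }
};

static Model* make_model(const std::string& name, List data) {
  if (name == "vbge") return new VbgeModel(data);
  if (name == "allo") return new AlloModel(data);
  if (name == "cc") return new CcModel(data);
  if (name == "lnorm") return new LnormModel(data);
  stop("unknown model '%s'", name);
  return nullptr;
}

// ---------------------------------------------------------------------------
// sampler

// Cholesky of a small dense matrix (row-major); returns false if not PD.
static bool chol_small(const std::vector<double>& A, int d,
                       std::vector<double>& L) {
  L.assign(d * d, 0.0);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * d + i] = std::sqrt(s);
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
  }
  return true;
}

// [[Rcpp::export(name = ".amwg_chain")]]
List amwg_chain(std::string model, List data, NumericVector init,
                NumericVector scale0, int iter, int warmup,
                double target_accept, int thin, List blocks,
                List shift_fam, List scale_fam) {
  Model* m = make_model(model, data);
  int d = m->d, n = m->n;
  if ((int)init.size() != d) { delete m; stop("init has length %d, model needs %d", (int)init.size(), d); }
  std::vector<double> th(init.begin(), init.end());
  std::vector<double> ls(d);
  for (int p = 0; p < d; ++p)
    ls[p] = std::log(scale0[(int)scale0.size() == d ? p : 0]);

  std::vector<double> pr(d), ll(n), tmp(n);
  double lpsum = 0.0, llsum = 0.0;
  for (int p = 0; p < d; ++p) { pr[p] = m->logprior_p(p, th[p]); lpsum += pr[p]; }
  for (int i = 0; i < n; ++i) { ll[i] = m->loglik_i(i, th.data()); llsum += ll[i]; }
  if (!std::isfinite(lpsum) || !std::isfinite(llsum)) {
    delete m;
    stop("initial values have zero posterior density");
  }

  if (thin < 1) thin = 1;
  int keep = (iter - warmup + thin - 1) / thin;
  NumericMatrix draws(keep, d);
  std::vector<int> acc(d, 0), tries(d, 0);
  int batch = 0;

  // Likelihood-invariant reparameterization moves for hierarchical families:
  // "shift" slides a hyper-mean while moving its group deviations so the
  // group-level values stay fixed; "rescale" multiplies a group SD while
  // dividing the deviations. Only priors and Jacobians enter the acceptance
  // ratio, so these moves are O(#groups) and break the slow random-walk
  // coupling between hyper-parameters and deviations.
  struct ShiftFam { int h; bool hlog; int s; std::vector<int> z; };
  struct ScaleFam { int s; std::vector<int> z; };
  std::vector<ShiftFam> sfam;
  std::vector<ScaleFam> cfam;
  for (int f = 0; f < shift_fam.size(); ++f) {
    List ff = shift_fam[f];
    ShiftFam sf;
    sf.h = as<int>(ff["h"]); sf.hlog = as<bool>(ff["hlog"]);
    sf.s = as<int>(ff["s"]); sf.z = as<std::vector<int> >(ff["z"]);
    sfam.push_back(sf);
  }
  for (int f = 0; f < scale_fam.size(); ++f) {
    List ff = scale_fam[f];
    ScaleFam cf;
    cf.s = as<int>(ff["s"]); cf.z = as<std::vector<int> >(ff["z"]);
    cfam.push_back(cf);
  }
  std::vector<double> sfam_ls(sfam.size(), std::log(0.1));
  std::vector<double> cfam_ls(cfam.size(), std::log(0.1));
  std::vector<int> sfam_acc(sfam.size(), 0), sfam_try(sfam.size(), 0);
  std::vector<int> cfam_acc(cfam.size(), 0), cfam_try(cfam.size(), 0);

  // adaptive multivariate block updates (handle correlated parameters):
  // each block proposes a joint Gaussian step whose covariance is learned
  // online during warmup (scaled 2.38^2/d), re-evaluating only the
  // observations its parameters can touch
  struct Block {
    std::vector<int> idx, aff;   // aff empty => all observations
    std::vector<double> mean, cov, chol;
    double count = 0.0, lscale = 0.0;
    int acc = 0, tries = 0;
    bool have_chol = false, aff_all = false;
  };
  std::vector<Block> blks;
  for (int f = 0; f < blocks.size(); ++f) {
    Block b;
    b.idx = as<std::vector<int> >(blocks[f]);
    int dbf = (int)b.idx.size();
    if (dbf < 2) continue;
    b.mean.assign(dbf, 0.0);
    b.cov.assign(dbf * dbf, 0.0);
    // union of affected observations; any global member forces a full pass
    for (int k = 0; k < dbf && !b.aff_all; ++k) {
      if (m->affected[b.idx[k]].empty()) b.aff_all = true;
      else b.aff.insert(b.aff.end(), m->affected[b.idx[k]].begin(),
                        m->affected[b.idx[k]].end());
    }
    if (!b.aff_all) {
      std::sort(b.aff.begin(), b.aff.end());
      b.aff.erase(std::unique(b.aff.begin(), b.aff.end()), b.aff.end());
    } else {
      b.aff.clear();
    }
    blks.push_back(b);
  }

  GetRNGstate();
  for (int it = 0; it < iter; ++it) {
    for (int p = 0; p < d; ++p) {
      double old = th[p];
      th[p] = old + std::exp(ls[p]) * norm_rand();
      double prn = m->logprior_p(p, th[p]);
      double delta = prn - pr[p];
      bool ok = std::isfinite(prn);
      const std::vector<int>& aff = m->affected[p];
      double dll = 0.0;
      if (ok) {
        if (aff.empty()) {
          for (int i = 0; i < n && ok; ++i) {
            tmp[i] = m->loglik_i(i, th.data());
            if (!std::isfinite(tmp[i])) ok = false; else dll += tmp[i] - ll[i];
          }
        } else {
          for (size_t k = 0; k < aff.size() && ok; ++k) {
            int i = aff[k];
            tmp[k] = m->loglik_i(i, th.data());
            if (!std::isfinite(tmp[k])) ok = false; else dll += tmp[k] - ll[i];
          }
        }
      }
      ++tries[p];
      if (ok && std::log(unif_rand()) < delta + dll) {
        pr[p] = prn; lpsum += delta; llsum += dll;
        if (aff.empty()) for (int i = 0; i < n; ++i) ll[i] = tmp[i];
        else for (size_t k = 0; k < aff.size(); ++k) ll[aff[k]] = tmp[k];
        ++acc[p];
      } else {
        th[p] = old;
      }
    }
    for (size_t bi = 0; bi < blks.size(); ++bi) {
      Block& B = blks[bi];
      int dbf = (int)B.idx.size();
      // learn the block covariance during warmup
      if (it < warmup) {
        B.count += 1.0;
        std::vector<double> dx(dbf);
        for (int i = 0; i < dbf; ++i) {
          dx[i] = th[B.idx[i]] - B.mean[i];
          B.mean[i] += dx[i] / B.count;
        }
        for (int i = 0; i < dbf; ++i)
          for (int j = 0; j < dbf; ++j)
            B.cov[i * dbf + j] += dx[i] * (th[B.idx[j]] - B.mean[j]);
        if ((it + 1) % 50 == 0 && B.count > 2.0 * dbf) {
          std::vector<double> A(dbf * dbf);
          double f = 5.6644 / dbf / (B.count - 1.0); // 2.38^2 / d
          for (int i = 0; i < dbf; ++i)
            for (int j = 0; j < dbf; ++j) {
              A[i * dbf + j] = f * B.cov[i * dbf + j];
              if (i == j) A[i * dbf + j] += 1e-10 + 1e-6 * f * B.cov[i * dbf + i];
            }
          B.have_chol = chol_small(A, dbf, B.chol);
        }
      }
      std::vector<double> old(dbf), eta(dbf), prn(dbf);
      for (int i = 0; i < dbf; ++i) eta[i] = norm_rand();
      double bm = std::exp(B.lscale);
      double dpr = 0.0, dll = 0.0;
      bool ok = true;
      for (int i = 0; i < dbf; ++i) {
        old[i] = th[B.idx[i]];
        double step = 0.0;
        if (B.have_chol)
          for (int k = 0; k <= i; ++k) step += B.chol[i * dbf + k] * eta[k];
        else
          step = scale0[B.idx[i]] * eta[i];
        th[B.idx[i]] = old[i] + bm * step;
      }
      for (int i = 0; i < dbf && ok; ++i) {
        prn[i] = m->logprior_p(B.idx[i], th[B.idx[i]]);
        if (!std::isfinite(prn[i])) ok = false;
        else dpr += prn[i] - pr[B.idx[i]];
      }
      if (ok) {
        if (B.aff_all) {
          for (int i = 0; i < n && ok; ++i) {
            tmp[i] = m->loglik_i(i, th.data());
            if (!std::isfinite(tmp[i])) ok = false; else dll += tmp[i] - ll[i];
          }
        } else {
          for (size_t k = 0; k < B.aff.size() && ok; ++k) {
            int i = B.aff[k];
            tmp[k] = m->loglik_i(i, th.data());
            if (!std::isfinite(tmp[k])) ok = false; else dll += tmp[k] - ll[i];
          }
        }
      }
      ++B.tries;
      if (ok && std::log(unif_rand()) < dpr + dll) {
        for (int i = 0; i < dbf; ++i) pr[B.idx[i]] = prn[i];
        lpsum += dpr; llsum += dll;
        if (B.aff_all) for (int i = 0; i < n; ++i) ll[i] = tmp[i];
        else for (size_t k = 0; k < B.aff.size(); ++k) ll[B.aff[k]] = tmp[k];
        ++B.acc;
      } else {
        for (int i = 0; i < dbf; ++i) th[B.idx[i]] = old[i];
      }
    }
    for (size_t f = 0; f < sfam.size(); ++f) {
      ShiftFam& sf = sfam[f];
      double mu = sf.hlog ? std::exp(th[sf.h]) : th[sf.h];
      double delta = std::exp(sfam_ls[f]) * norm_rand();
      double mun = mu + delta;
      ++sfam_try[f];
      if (sf.hlog && mun <= 0.0) continue;
      double hn = sf.hlog ? std::log(mun) : mun;
      double s = std::exp(th[sf.s]);
      double prn_h = m->logprior_p(sf.h, hn);
      double dprior = prn_h - pr[sf.h];
      std::vector<double> zn(sf.z.size()), przn(sf.z.size());
      for (size_t k = 0; k < sf.z.size(); ++k) {
        zn[k] = th[sf.z[k]] - delta / s;
        przn[k] = m->logprior_p(sf.z[k], zn[k]);
        dprior += przn[k] - pr[sf.z[k]];
      }
      double jac = sf.hlog ? std::log(mu) - std::log(mun) : 0.0;
      if (std::isfinite(dprior) &&
          std::log(unif_rand()) < dprior + jac) {
        th[sf.h] = hn; pr[sf.h] = prn_h;
        for (size_t k = 0; k < sf.z.size(); ++k) {
          th[sf.z[k]] = zn[k]; pr[sf.z[k]] = przn[k];
        }
        lpsum += dprior;
        ++sfam_acc[f];
      }
    }
    for (size_t f = 0; f < cfam.size(); ++f) {
      ScaleFam& cf = cfam[f];
      double eta = std::exp(cfam_ls[f]) * norm_rand();
      ++cfam_try[f];
      double lsn = th[cf.s] + eta;
      double prn_s = m->logprior_p(cf.s, lsn);
      double dlp = prn_s - pr[cf.s] - eta * (double)cf.z.size();
      std::vector<double> zn(cf.z.size()), przn(cf.z.size());
      double fac = std::exp(-eta);
      for (size_t k = 0; k < cf.z.size(); ++k) {
        zn[k] = th[cf.z[k]] * fac;
        przn[k] = m->logprior_p(cf.z[k], zn[k]);
        dlp += przn[k] - pr[cf.z[k]];
      }
      if (std::isfinite(dlp) && std::log(unif_rand()) < dlp) {
        for (size_t k = 0; k < cf.z.size(); ++k) {
          lpsum += przn[k] - pr[cf.z[k]];
          th[cf.z[k]] = zn[k]; pr[cf.z[k]] = przn[k];
        }
        lpsum += prn_s - pr[cf.s];
        th[cf.s] = lsn; pr[cf.s] = prn_s;
        ++cfam_acc[f];
      }
    }
    if (it < warmup && (it + 1) % 50 == 0) {
      ++batch;
      double step = std::min(0.5, 1.0 / std::sqrt((double)batch));
      for (int p = 0; p < d; ++p) {
        double rate = tries[p] ? (double)acc[p] / tries[p] : 0.0;
        ls[p] += (rate > target_accept ? step : -step);
        acc[p] = 0; tries[p] = 0;
      }
      for (size_t bi = 0; bi < blks.size(); ++bi) {
        Block& B = blks[bi];
        if (B.tries > 0) {
          double brate = (double)B.acc / B.tries;
          B.lscale += (brate > 0.234 ? step : -step);
          B.acc = 0; B.tries = 0;
        }
      }
      for (size_t f = 0; f < sfam.size(); ++f) {
        if (sfam_try[f] > 0) {
          double r0 = (double)sfam_acc[f] / sfam_try[f];
          sfam_ls[f] += (r0 > target_accept ? step : -step);
          sfam_acc[f] = 0; sfam_try[f] = 0;
        }
      }
      for (size_t f = 0; f < cfam.size(); ++f) {
        if (cfam_try[f] > 0) {
          double r0 = (double)cfam_acc[f] / cfam_try[f];
          cfam_ls[f] += (r0 > target_accept ? step : -step);
          cfam_acc[f] = 0; cfam_try[f] = 0;
        }
      }
    }
    if ((it + 1) % 500 == 0) { // guard against float drift in the running sum
      llsum = 0.0; for (int i = 0; i < n; ++i) llsum += ll[i];
    }
    if (it == warmup / 2) {
      // discard pre-convergence history from the block covariance estimates
      for (size_t bi = 0; bi < blks.size(); ++bi) {
        Block& B = blks[bi];
        B.count = 0.0;
        std::fill(B.mean.begin(), B.mean.end(), 0.0);
        std::fill(B.cov.begin(), B.cov.end(), 0.0);
      }
    }
    if (it >= warmup && (it - warmup) % thin == 0)
      for (int p = 0; p < d; ++p) draws((it - warmup) / thin, p) = th[p];
  }
  PutRNGstate();

  NumericVector rate(d), scales(d);
  for (int p = 0; p < d; ++p) {
    rate[p] = tries[p] ? (double)acc[p] / tries[p] : NA_REAL;
    scales[p] = std::exp(ls[p]);
  }
  delete m;
  return List::create(_["draws"] = draws, _["accept"] = rate,
                      _["scales"] = scales, _["lp"] = lpsum + llsum);
}

// [[Rcpp::export(name = ".model_dim")]]
int model_dim(std::string model, List data) {
  Model* m = make_model(model, data);
  int d = m->d;
  delete m;
  return d;
}

// [[Rcpp::export(name = ".model_logpost")]]
double model_logpost(std::string model, List data, NumericVector theta) {
  Model* m = make_model(model, data);
  if ((int)theta.size() != m->d) { delete m; stop("theta has wrong length"); }
  double lp = m->logprior(theta.begin());
  if (std::isfinite(lp))
    for (int i = 0; i < m->n; ++i) {
      lp += m->loglik_i(i, theta.begin());
      if (!std::isfinite(lp)) break;
    }
  delete m;
  return lp;
}

// Pointwise log-likelihood matrix (draws x observations), for LOO-CV.
// [[Rcpp::export(name = ".model_loglik")]]
NumericMatrix model_loglik(std::string model, List data, NumericMatrix draws) {
  Model* m = make_model(model, data);
  int S = draws.nrow(), n = m->n;
  if (draws.ncol() != m->d) { delete m; stop("draws have wrong dimension"); }
  NumericMatrix out(S, n);
  std::vector<double> th(m->d);
  for (int s = 0; s < S; ++s) {
    for (int p = 0; p < m->d; ++p) th[p] = draws(s, p);
    for (int i = 0; i < n; ++i) out(s, i) = m->loglik_i(i, th.data());
  }
  delete m;
  return out;
}
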