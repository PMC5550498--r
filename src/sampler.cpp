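// Adaptive Metropolis-within-Gibbs sampler for hierarchical Bayesian
// space-time Poisson models on areal panels.
//
// Latent state: alpha (intercept), beta (linear covariate coefficients),
// gamma + delta_i (grand linear trend + area differential slopes) OR
// phi_t + psi_t (RW2 + iid dynamic trend), u_i (ICAR) + v_i (iid) BYM
// residuals, f_k (RW2 effects over binned covariate values).
// Precisions get conjugate Gamma updates from the scaled structure
// quadratic forms. All randomness goes through R's RNG so runs are
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Adapt {
  std::vector<double> ls;    // log proposal sd
  std::vector<int> acc, att;
  void init(int k, double s0) {
    ls.assign(k, std::log(s0));
    acc.assign(k, 0);
    att.assign(k, 0);
  }
  void tune(double step) {  // Roberts-Rosenthal batch adaptation, target 0.44
    for (size_t j = 0; j < ls.size(); ++j) {
      if (att[j] == 0) continue;
      double rate = (double)acc[j] / att[j];
      ls[j] += (rate > 0.44 ? step : -step);
      acc[j] = 0;
      att[j] = 0;
    }
  }
};

// log-likelihood change over a set of cells for per-cell shift d[c]:
// sum y*d - M*(exp(d)-1), with M = E*exp(eta) cached.
inline double dll_const(const double* y, const double* M, const int* cells,
                        int k, double d) {
  double sy = 0.0, sm = 0.0;
  for (int c = 0; c < k; ++c) {
    sy += y[cells[c]];
    sm += M[cells[c]];
  }
  return d * sy - (std::exp(d) - 1.0) * sm;
}

inline void apply_const(double* eta, double* M, const int* cells, int k,
                        double d) {
  double ed = std::exp(d);
  for (int c = 0; c < k; ++c) {
    eta[cells[c]] += d;
    M[cells[c]] *= ed;
  }
}

// dense lower Cholesky of row-major A (m x m), in place; false if not PD
bool chol_lower(std::vector<double>& A, int m) {
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * m + j];
      for (int k = 0; k < j; ++k) s -= A[i * m + k] * A[j * m + k];
      if (i == j) {
        if (s <= 0.0) return false;
        A[i * m + i] = std::sqrt(s);
      } else {
        A[i * m + j] = s / A[j * m + j];
      }
    }
    for (int j = i + 1; j < m; ++j) A[i * m + j] = 0.0;
  }
  return true;
}

void solve_L(const std::vector<double>& L, int m, std::vector<double>& b) {
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * m + k] * b[k];
    b[i] = s / L[i * m + i];
  }
}

void solve_Lt(const std::vector<double>& L, int m, std::vector<double>& b) {
  for (int i = m - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < m; ++k) s -= L[k * m + i] * b[k];
    b[i] = s / L[i * m + i];
  }
}

}  // namespace

// [[Rcpp::export(name = ".st_mcmc")]]
List st_mcmc(NumericMatrix y, NumericMatrix E, List Xlin, List fbin_cells,
             List Qf, List nbr, IntegerVector comp, double icar_scale,
             Nullable<NumericMatrix> Qphi_, NumericVector tvec,
             bool trend_linear, bool include_residual, double prec0,
             List prior, int n_iter, int burnin, int thin) {
  const int n = y.nrow(), T = y.ncol(), ncell = n * T;
  const int K = Xlin.size();
  const int KF = Qf.size();
  if (n_iter <= burnin) stop("n_iter must exceed burnin");

  // cached state
  std::vector<double> eta(ncell, 0.0), M(ncell);
  for (int c = 0; c < ncell; ++c) M[c] = E[c];

  double alpha = 0.0, gamma = 0.0;
  std::vector<double> beta(K, 0.0), delta(n, 0.0), u(n, 0.0), v(n, 0.0);
  std::vector<std::vector<double>> f(KF);
  std::vector<int> mf(KF);
  for (int k = 0; k < KF; ++k) {
    mf[k] = as<NumericMatrix>(Qf[k]).nrow();
    f[k].assign(mf[k], 0.0);
  }
  std::vector<double> phi(T, 0.0), psi(T, 0.0);
  double tau_u = 1, tau_v = 1, tau_d = 1, tau_phi = 1, tau_psi = 1;
  std::vector<double> tau_f(KF, 1.0);

  // adjacency
  std::vector<std::vector<int>> adj(n);
  int ncomp = 0;
  for (int i = 0; i < n; ++i) {
    IntegerVector a = nbr[i];
    adj[i] = std::vector<int>(a.begin(), a.end());
    if (comp[i] + 1 > ncomp) ncomp = comp[i] + 1;
  }

  // per-area cell index lists (column-major: cell = i + n*t)
  std::vector<std::vector<int>> area_cells(n);
  for (int i = 0; i < n; ++i) {
    area_cells[i].resize(T);
    for (int t = 0; t < T; ++t) area_cells[i][t] = i + n * t;
  }
  // per-period cell lists
  std::vector<std::vector<int>> per_cells(T);
  for (int t = 0; t < T; ++t) {
    per_cells[t].resize(n);
    for (int i = 0; i < n; ++i) per_cells[t][i] = i + n * t;
  }
  // rw2 covariate bin -> cell lists
  std::vector<std::vector<std::vector<int>>> bin_cells(KF);
  for (int k = 0; k < KF; ++k) {
    List bl = fbin_cells[k];
    bin_cells[k].resize(bl.size());
    for (int j = 0; j < bl.size(); ++j) {
      IntegerVector cv = bl[j];
      bin_cells[k][j] = std::vector<int>(cv.begin(), cv.end());
    }
  }

  NumericMatrix Qphi = Qphi_.isNotNull() ? as<NumericMatrix>(Qphi_)
                                         : NumericMatrix(0, 0);

  // priors
  const double a_u = prior["a_u"], b_u = prior["b_u"];
  const double a_v = prior["a_v"], b_v = prior["b_v"];
  const double a_d = prior["a_delta"], b_d = prior["b_delta"];
  const double a_phi = prior["a_phi"], b_phi = prior["b_phi"];
  const double a_psi = prior["a_psi"], b_psi = prior["b_psi"];
  NumericVector a_f = prior["a_f"], b_f = prior["b_f"];

  // proposal scales
  Adapt ad_alpha, ad_beta, ad_gamma, ad_delta, ad_u, ad_v, ad_phi, ad_psi;
  std::vector<Adapt> ad_f(KF);
  ad_alpha.init(1, 0.1);
  ad_beta.init(K, 0.01);
  ad_gamma.init(1, 0.05);
  ad_delta.init(n, 0.05);
  ad_u.init(n, 0.1);
  ad_v.init(n, 0.1);
  ad_phi.init(T, 0.05);
  ad_psi.init(T, 0.05);
  // one adaptive scale per RW2 field: the log-precision step of its
  // joint (tau, field) block move
  for (int k = 0; k < KF; ++k) ad_f[k].init(1, 0.5);

  // storage
  const int S = (n_iter - burnin) / thin;
  NumericVector s_alpha(S), s_gamma(S), s_tau_u(S), s_tau_v(S), s_tau_d(S),
      s_tau_phi(S), s_tau_psi(S), s_dev(S);
  NumericMatrix s_beta(S, K), s_delta(S, n), s_u(S, n), s_v(S, n),
      s_phi(S, T), s_psi(S, T);
  List s_f(KF), s_tau_f(KF);
  std::vector<NumericMatrix> sf(KF);
  std::vector<NumericVector> stf(KF);
  for (int k = 0; k < KF; ++k) {
    sf[k] = NumericMatrix(S, mf[k]);
    stf[k] = NumericVector(S);
  }

  RNGScope scope;
  const double* yp = y.begin();
  std::vector<int> all_cells(ncell);
  for (int c = 0; c < ncell; ++c) all_cells[c] = c;

  int stored = 0, batch = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- alpha: global constant shift ---
    {
      double d = R::rnorm(0.0, std::exp(ad_alpha.ls[0]));
      double lr = dll_const(yp, M.data(), all_cells.data(), ncell, d);
      lr += -0.5 * prec0 * ((alpha + d) * (alpha + d) - alpha * alpha);
      ad_alpha.att[0]++;
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        apply_const(eta.data(), M.data(), all_cells.data(), ncell, d);
        alpha += d;
        ad_alpha.acc[0]++;
      }
    }

    // --- beta_k: shift proportional to covariate ---
    for (int k = 0; k < K; ++k) {
      NumericMatrix X = Xlin[k];
      double db = R::rnorm(0.0, std::exp(ad_beta.ls[k]));
      double lr = 0.0;
      for (int c = 0; c < ncell; ++c) {
        double d = db * X[c];
        lr += yp[c] * d - M[c] * (std::exp(d) - 1.0);
      }
      double bn = beta[k] + db;
      lr += -0.5 * prec0 * (bn * bn - beta[k] * beta[k]);
      ad_beta.att[k]++;
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        for (int c = 0; c < ncell; ++c) {
          double d = db * X[c];
          eta[c] += d;
          M[c] *= std::exp(d);
        }
        beta[k] = bn;
        ad_beta.acc[k]++;
      }
    }

    if (trend_linear) {
      // --- gamma: shift proportional to centred time ---
      {
        double dg = R::rnorm(0.0, std::exp(ad_gamma.ls[0]));
        double lr = 0.0;
        for (int t = 0; t < T; ++t) {
          double d = dg * tvec[t];
          if (d == 0.0) continue;
          double sy = 0.0, sm = 0.0;
          for (int i = 0; i < n; ++i) {
            sy += yp[i + n * t];
            sm += M[i + n * t];
          }
          lr += d * sy - (std::exp(d) - 1.0) * sm;
        }
        double gn = gamma + dg;
        lr += -0.5 * prec0 * (gn * gn - gamma * gamma);
        ad_gamma.att[0]++;
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          for (int t = 0; t < T; ++t) {
            double d = dg * tvec[t];
            double ed = std::exp(d);
            for (int i = 0; i < n; ++i) {
              eta[i + n * t] += d;
              M[i + n * t] *= ed;
            }
          }
          gamma = gn;
          ad_gamma.acc[0]++;
        }
      }
      // --- delta_i: area differential slopes ---
      for (int i = 0; i < n; ++i) {
        double dd = R::rnorm(0.0, std::exp(ad_delta.ls[i]));
        double lr = 0.0;
        for (int t = 0; t < T; ++t) {
          double d = dd * tvec[t];
          int c = i + n * t;
          lr += yp[c] * d - M[c] * (std::exp(d) - 1.0);
        }
        double dn = delta[i] + dd;
        lr += -0.5 * tau_d * (dn * dn - delta[i] * delta[i]);
        ad_delta.att[i]++;
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          for (int t = 0; t < T; ++t) {
            int c = i + n * t;
            double d = dd * tvec[t];
            eta[c] += d;
            M[c] *= std::exp(d);
          }
          delta[i] = dn;
          ad_delta.acc[i]++;
        }
      }
      // re-project: mean(delta) -> gamma (eta invariant)
      double md = 0.0;
      for (int i = 0; i < n; ++i) md += delta[i];
      md /= n;
      for (int i = 0; i < n; ++i) delta[i] -= md;
      gamma += md;
    } else {
      // --- phi_t: RW2 dynamic trend ---
      for (int t = 0; t < T; ++t) {
        double d = R::rnorm(0.0, std::exp(ad_phi.ls[t]));
        double lr = dll_const(yp, M.data(), per_cells[t].data(), n, d);
        double r = 0.0;
        for (int l = 0; l < T; ++l) r += Qphi(t, l) * phi[l];
        r -= Qphi(t, t) * phi[t];
        double pn = phi[t] + d;
        lr += -0.5 * tau_phi *
              (Qphi(t, t) * (pn * pn - phi[t] * phi[t]) + 2.0 * d * r);
        ad_phi.att[t]++;
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          apply_const(eta.data(), M.data(), per_cells[t].data(), n, d);
          phi[t] = pn;
          ad_phi.acc[t]++;
        }
      }
      // --- psi_t: iid period effect ---
      for (int t = 0; t < T; ++t) {
        double d = R::rnorm(0.0, std::exp(ad_psi.ls[t]));
        double lr = dll_const(yp, M.data(), per_cells[t].data(), n, d);
        double pn = psi[t] + d;
        lr += -0.5 * tau_psi * (pn * pn - psi[t] * psi[t]);
        ad_psi.att[t]++;
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          apply_const(eta.data(), M.data(), per_cells[t].data(), n, d);
          psi[t] = pn;
          ad_psi.acc[t]++;
        }
      }
      // re-project means into alpha (eta invariant)
      double mp = 0.0, mq = 0.0;
      for (int t = 0; t < T; ++t) {
        mp += phi[t];
        mq += psi[t];
      }
      mp /= T;
      mq /= T;
      for (int t = 0; t < T; ++t) {
        phi[t] -= mp;
        psi[t] -= mq;
      }
      alpha += mp + mq;
    }

    if (include_residual) {
      // --- u_i: ICAR (full conditional prior: neighbour mean) ---
      for (int i = 0; i < n; ++i) {
        int deg = adj[i].size();
        if (deg == 0) continue;  // island: point-constrained at zero
        double d = R::rnorm(0.0, std::exp(ad_u.ls[i]));
        double lr = dll_const(yp, M.data(), area_cells[i].data(), T, d);
        double snb = 0.0;
        for (int j : adj[i]) snb += u[j];
        double un = u[i] + d;
        lr += -0.5 * tau_u * icar_scale *
              (deg * (un * un - u[i] * u[i]) - 2.0 * d * snb);
        ad_u.att[i]++;
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          apply_const(eta.data(), M.data(), area_cells[i].data(), T, d);
          u[i] = un;
          ad_u.acc[i]++;
        }
      }
      // re-project: per-component mean of u -> v (eta invariant)
      std::vector<double> cm(ncomp, 0.0);
      std::vector<int> cn(ncomp, 0);
      for (int i = 0; i < n; ++i) {
        cm[comp[i]] += u[i];
        cn[comp[i]]++;
      }
      for (int c = 0; c < ncomp; ++c) cm[c] /= cn[c];
      for (int i = 0; i < n; ++i) {
        u[i] -= cm[comp[i]];
        v[i] += cm[comp[i]];
      }
      // --- v_i: iid residual ---
      for (int i = 0; i < n; ++i) {
        double d = R::rnorm(0.0, std::exp(ad_v.ls[i]));
        double lr = dll_const(yp, M.data(), area_cells[i].data(), T, d);
        double vn = v[i] + d;
        lr += -0.5 * tau_v * (vn * vn - v[i] * v[i]);
        ad_v.att[i]++;
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          apply_const(eta.data(), M.data(), area_cells[i].data(), T, d);
          v[i] = vn;
          ad_v.acc[i]++;
        }
      }
    }

    // --- f_k: RW2 covariate effects, joint one-block (tau, field) update ---
    // Propose tau' by log random walk, then the whole field from the
    // Gaussian (Taylor) approximation of its Poisson full conditional at
    // tau' (Knorr-Held/Rue style one-block move). This is what keeps the
    // field-precision pair mixing; single-site updates leave it stuck in
    // an under-smoothed regime for fields with many bins.
    for (int k = 0; k < KF; ++k) {
      NumericMatrix Q = Qf[k];
      int m = mf[k];
      std::vector<double>& fk = f[k];
      // bin-level sufficient statistics of the current Poisson weights
      std::vector<double> wj(m, 0.0), sy(m, 0.0);
      for (int j = 0; j < m; ++j) {
        for (int c : bin_cells[k][j]) {
          wj[j] += M[c];
          sy[j] += yp[c];
        }
      }
      double tau0 = tau_f[k];
      double tau1 = tau0 * std::exp(R::rnorm(0.0, std::exp(ad_f[k].ls[0])));
      // forward proposal: N(mu1, P1^-1), P1 = tau1*Q + diag(w),
      // canonical b1 = (y - M) + w * f  (Taylor at the current field)
      std::vector<double> P1(m * m), b1(m), z(m), fprop(m);
      for (int i2 = 0; i2 < m; ++i2) {
        for (int j2 = 0; j2 < m; ++j2) P1[i2 * m + j2] = tau1 * Q(i2, j2);
        P1[i2 * m + i2] += wj[i2];
        b1[i2] = (sy[i2] - wj[i2]) + wj[i2] * fk[i2];
      }
      if (!chol_lower(P1, m)) continue;
      double logdet1 = 0.0;
      for (int i2 = 0; i2 < m; ++i2) logdet1 += 2.0 * std::log(P1[i2 * m + i2]);
      std::vector<double> mu1 = b1;
      solve_L(P1, m, mu1);
      solve_Lt(P1, m, mu1);
      double zz = 0.0;
      for (int i2 = 0; i2 < m; ++i2) {
        z[i2] = R::rnorm(0.0, 1.0);
        zz += z[i2] * z[i2];
      }
      std::vector<double> pert = z;
      solve_Lt(P1, m, pert);
      for (int i2 = 0; i2 < m; ++i2) fprop[i2] = mu1[i2] + pert[i2];
      // log-likelihood change and reverse-state bin weights, all bin-level
      // (every cell in bin j shifts by the same d_j)
      double dll = 0.0;
      std::vector<double> w2(m), b2(m), P2(m * m);
      bool ok = true;
      for (int j = 0; j < m; ++j) {
        double d = fprop[j] - fk[j];
        if (d > 30.0) { ok = false; break; }
        double ed = std::exp(d);
        dll += sy[j] * d - wj[j] * (ed - 1.0);
        w2[j] = wj[j] * ed;
      }
      if (!ok) continue;
      for (int i2 = 0; i2 < m; ++i2) {
        for (int j2 = 0; j2 < m; ++j2) P2[i2 * m + j2] = tau0 * Q(i2, j2);
        P2[i2 * m + i2] += w2[i2];
        b2[i2] = (sy[i2] - w2[i2]) + w2[i2] * fprop[i2];
      }
      if (!chol_lower(P2, m)) continue;
      double logdet2 = 0.0;
      for (int i2 = 0; i2 < m; ++i2) logdet2 += 2.0 * std::log(P2[i2 * m + i2]);
      std::vector<double> mu2 = b2;
      solve_L(P2, m, mu2);
      solve_Lt(P2, m, mu2);
      // q densities: forward quadratic form is z'z by construction
      double lq_fwd = 0.5 * logdet1 - 0.5 * zz;
      std::vector<double> diff(m);
      for (int i2 = 0; i2 < m; ++i2) diff[i2] = fk[i2] - mu2[i2];
      // (f - mu2)' P2 (f - mu2) via the Cholesky factor: ||L2' diff||^2
      double qf2 = 0.0;
      for (int i2 = 0; i2 < m; ++i2) {
        double s = 0.0;
        for (int j2 = i2; j2 < m; ++j2) s += P2[j2 * m + i2] * diff[j2];
        qf2 += s * s;
      }
      double lq_rev = 0.5 * logdet2 - 0.5 * qf2;
      // GMRF prior (rank m-2) and Gamma prior on tau (with log-scale Jacobian)
      double q_old = 0.0, q_new = 0.0;
      for (int i2 = 0; i2 < m; ++i2) {
        for (int j2 = 0; j2 < m; ++j2) {
          q_old += fk[i2] * Q(i2, j2) * fk[j2];
          q_new += fprop[i2] * Q(i2, j2) * fprop[j2];
        }
      }
      double lr = dll +
                  0.5 * (m - 2) * (std::log(tau1) - std::log(tau0)) -
                  0.5 * (tau1 * q_new - tau0 * q_old) +
                  a_f[k] * (std::log(tau1) - std::log(tau0)) -
                  b_f[k] * (tau1 - tau0) +
                  lq_rev - lq_fwd;
      ad_f[k].att[0]++;
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        for (int j = 0; j < m; ++j) {
          double d = fprop[j] - fk[j];
          if (d != 0.0 && !bin_cells[k][j].empty()) {
            apply_const(eta.data(), M.data(), bin_cells[k][j].data(),
                        bin_cells[k][j].size(), d);
          }
        }
        fk = fprop;
        tau_f[k] = tau1;
        ad_f[k].acc[0]++;
      }
      // re-project: mean(f) -> alpha. Subtracting mean(f) from every bin and
      // adding it to alpha is exactly eta-invariant (one f value per cell).
      double mfk = 0.0;
      for (int j = 0; j < m; ++j) mfk += fk[j];
      mfk /= m;
      for (int j = 0; j < m; ++j) fk[j] -= mfk;
      alpha += mfk;
    }

    // --- conjugate precision updates ---
    if (include_residual) {
      double qf = 0.0;
      for (int i = 0; i < n; ++i)
        for (int j : adj[i])
          if (j > i) qf += (u[i] - u[j]) * (u[i] - u[j]);
      qf *= icar_scale;
      tau_u = R::rgamma(a_u + 0.5 * (n - ncomp), 1.0 / (b_u + 0.5 * qf));
      double sv = 0.0;
      for (int i = 0; i < n; ++i) sv += v[i] * v[i];
      tau_v = R::rgamma(a_v + 0.5 * n, 1.0 / (b_v + 0.5 * sv));
    }
    if (trend_linear) {
      double sd2 = 0.0;
      for (int i = 0; i < n; ++i) sd2 += delta[i] * delta[i];
      tau_d = R::rgamma(a_d + 0.5 * n, 1.0 / (b_d + 0.5 * sd2));
    } else {
      double qp = 0.0;
      for (int t = 0; t < T; ++t)
        for (int l = 0; l < T; ++l) qp += phi[t] * Qphi(t, l) * phi[l];
      tau_phi = R::rgamma(a_phi + 0.5 * (T - 2), 1.0 / (b_phi + 0.5 * qp));
      double sp = 0.0;
      for (int t = 0; t < T; ++t) sp += psi[t] * psi[t];
      tau_psi = R::rgamma(a_psi + 0.5 * T, 1.0 / (b_psi + 0.5 * sp));
    }
    for (int k = 0; k < KF; ++k) {
      NumericMatrix Q = Qf[k];
      int m = mf[k];
      double qf = 0.0;
      for (int j = 0; j < m; ++j)
        for (int l = 0; l < m; ++l) qf += f[k][j] * Q(j, l) * f[k][l];
      tau_f[k] =
          R::rgamma(a_f[k] + 0.5 * (m - 2), 1.0 / (b_f[k] + 0.5 * qf));
    }

    // adaptation during burn-in only (frozen afterwards for ergodicity)
    if (it < burnin && (it + 1) % 50 == 0) {
      batch++;
      double step = std::min(0.25, 1.0 / std::sqrt((double)batch));
      ad_alpha.tune(step);
      ad_beta.tune(step);
      ad_gamma.tune(step);
      ad_delta.tune(step);
      ad_u.tune(step);
      ad_v.tune(step);
      ad_phi.tune(step);
      ad_psi.tune(step);
      for (int k = 0; k < KF; ++k) ad_f[k].tune(step);
    }

    // divergence guard
    if ((it + 1) % 100 == 0) {
      for (int c = 0; c < ncell; ++c) {
        if (std::fabs(eta[c]) > 50.0) {
          stop("divergent chain: |eta| > 50 at iteration %d", it + 1);
        }
      }
      Rcpp::checkUserInterrupt();
    }

    // storage
    if (it >= burnin && (it - burnin) % thin == 0 && stored < S) {
      s_alpha[stored] = alpha;
      s_gamma[stored] = gamma;
      for (int k = 0; k < K; ++k) s_beta(stored, k) = beta[k];
      for (int i = 0; i < n; ++i) {
        s_delta(stored, i) = delta[i];
        s_u(stored, i) = u[i];
        s_v(stored, i) = v[i];
      }
      for (int t = 0; t < T; ++t) {
        s_phi(stored, t) = phi[t];
        s_psi(stored, t) = psi[t];
      }
      for (int k = 0; k < KF; ++k) {
        for (int j = 0; j < mf[k]; ++j) sf[k](stored, j) = f[k][j];
        stf[k][stored] = tau_f[k];
      }
      s_tau_u[stored] = tau_u;
      s_tau_v[stored] = tau_v;
      s_tau_d[stored] = tau_d;
      s_tau_phi[stored] = tau_phi;
      s_tau_psi[stored] = tau_psi;
      // deviance of the current draw
      double ll = 0.0;
      for (int c = 0; c < ncell; ++c) {
        ll += yp[c] * (std::log(E[c]) + eta[c]) - M[c] - R::lgammafn(yp[c] + 1.0);
      }
      s_dev[stored] = -2.0 * ll;
      stored++;
    }
  }

  for (int k = 0; k < KF; ++k) {
    s_f[k] = sf[k];
    s_tau_f[k] = stf[k];
  }

  // mean acceptance rates per block (post-burn-in attempts)
  auto rate = [](const Adapt& a) {
    double num = 0, den = 0;
    for (size_t j = 0; j < a.ls.size(); ++j) {
      num += a.acc[j];
      den += a.att[j];
    }
    return den > 0 ? num / den : NA_REAL;
  };
  NumericVector acc = NumericVector::create(
      _["alpha"] = rate(ad_alpha), _["beta"] = rate(ad_beta),
      _["gamma"] = rate(ad_gamma), _["delta"] = rate(ad_delta),
      _["u"] = rate(ad_u), _["v"] = rate(ad_v), _["phi"] = rate(ad_phi),
      _["psi"] = rate(ad_psi));

  return List::create(
      _["alpha"] = s_alpha, _["beta"] = s_beta, _["gamma"] = s_gamma,
      _["delta"] = s_delta, _["u"] = s_u, _["v"] = s_v, _["phi"] = s_phi,
      _["psi"] = s_psi, _["f"] = s_f, _["tau_u"] = s_tau_u,
      _["tau_v"] = s_tau_v, _["tau_delta"] = s_tau_d,
      _["tau_phi"] = s_tau_phi, _["tau_psi"] = s_tau_psi,
      _["tau_f"] = s_tau_f, _["deviance"] = s_dev,
      _["acceptance"] = acc);
}
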