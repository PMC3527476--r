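#include <Rcpp.h>
using namespace Rcpp;

// Pedigree codes: individuals 0..n-1 in topological order (parents precede
// offspring); -1 marks an unknown parent.

static double mendelian_var(int s, int d, const std::vector<double> &F) {
  // variance of the Mendelian-sampling deviation, in units of sigma2_u
  if (s < 0 && d < 0) return 1.0;
  if (s < 0) return 0.75 - 0.25 * F[d];
  if (d < 0) return 0.75 - 0.25 * F[s];
  return 0.5 - 0.25 * (F[s] + F[d]);
}

// Meuwissen & Luo (1992) style inbreeding: F_i = a(s_i, d_i)/2, obtained by
// expanding the generalized Cholesky row of animal i over its ancestors:
// a_ii = sum_j L_ij^2 D_j = 1 + F_i.
// [[Rcpp::export]]
NumericVector inbreeding_ml(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  std::vector<double> F(n, 0.0), D(n, 1.0), L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s >= i || d >= i) {
      if (s == i || d == i) stop("individual is its own parent");
      if (s >= 0 && s >= i) stop("pedigree not ordered: sire after offspring");
      if (d >= 0 && d >= i) stop("pedigree not ordered: dam after offspring");
    }
    D[i] = mendelian_var(s, d, F);
    if (s < 0 || d < 0) { F[i] = 0.0; continue; }
    // accumulate a_ii for a virtual row anchored at i
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double acc = 0.0;
    for (int j = i; j >= 0; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      acc += lj * lj * D[j];
      int sj = sire[j], dj = dam[j];
      if (sj >= 0) L[sj] += 0.5 * lj;
      if (dj >= 0) L[dj] += 0.5 * lj;
    }
    F[i] = acc - 1.0;
  }
  return wrap(F);
}

// Henderson's rules for the sparse inverse numerator relationship matrix with
// inbreeding-corrected Mendelian-sampling variances. Returns triplets; the R
// side accumulates duplicates into a dgCMatrix.
// [[Rcpp::export]]
List ainverse_triplets(IntegerVector sire, IntegerVector dam,
                       NumericVector F) {
  const int n = sire.size();
  std::vector<double> Fv(F.begin(), F.end());
  std::vector<int> ri, ci;
  std::vector<double> xi;
  ri.reserve(9 * n); ci.reserve(9 * n); xi.reserve(9 * n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    double Dv = mendelian_var(s, d, Fv);
    if (Dv <= 0.0)
      stop("non-positive Mendelian-sampling variance at individual %d", i + 1);
    double w = 1.0 / Dv;
    ri.push_back(i); ci.push_back(i); xi.push_back(w);
    int par[2] = {s, d};
    for (int a = 0; a < 2; ++a) {
      if (par[a] < 0) continue;
      ri.push_back(par[a]); ci.push_back(i); xi.push_back(-0.5 * w);
      ri.push_back(i); ci.push_back(par[a]); xi.push_back(-0.5 * w);
      for (int b = 0; b < 2; ++b) {
        if (par[b] < 0) continue;
        ri.push_back(par[a]); ci.push_back(par[b]); xi.push_back(0.25 * w);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["x"] = wrap(xi));
}

static inline double dotv(const std::vector<double> &a,
                          const std::vector<double> &b) {
  double s = 0.0;
  for (size_t k = 0; k < a.size(); ++k) s += a[k] * b[k];
  return s;
}

// Single-site Gibbs sampler for the animal model
//   y = W theta + e,  theta = (b, u),  u ~ N(0, A sigma2_u),  flat prior on b,
//   sigma2_u ~ ScInvChi2(nu_u, S2u), sigma2_e ~ ScInvChi2(nu_e, S2e).
// W'W, W'y and A^-1 are passed in CSC pieces; the u block occupies columns
// u_off..p-1 of W. Maintains v1 = W'W theta and v2 = A^-1 u incrementally.
// fix_su2 / fix_se2 > 0 freeze the corresponding variance (no draw).
// [[Rcpp::export]]
List animal_gibbs_cpp(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                      NumericVector Wty, double yty, int n_obs,
                      IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                      int u_off,
                      double nu_u, double S2u, double nu_e, double S2e,
                      int n_iter, int burn_in, IntegerVector keep,
                      double fix_su2, double fix_se2, int refresh) {
  const int p = Wty.size();
  const int q = p - u_off;
  if (q < 0) stop("u_off exceeds parameter count");
  std::vector<double> theta(p, 0.0), v1(p, 0.0), v2(q, 0.0);
  std::vector<double> wdiag(p, 0.0), adiag(q, 0.0);
  for (int j = 0; j < p; ++j)
    for (int k = Wp[j]; k < Wp[j + 1]; ++k)
      if (Wi[k] == j) wdiag[j] = Wx[k];
  for (int j = 0; j < q; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] == j) adiag[j] = Ax[k];

  double su2 = (fix_su2 > 0.0) ? fix_su2 : S2u;
  double se2 = (fix_se2 > 0.0) ? fix_se2 : S2e;
  if (su2 <= 0.0 || se2 <= 0.0) stop("initial variances must be positive");
  double alpha = se2 / su2;

  const int n_keep = n_iter - burn_in;
  if (n_keep <= 0) stop("burn_in must be smaller than n_iter");
  NumericVector su_chain(n_keep), se_chain(n_keep);
  NumericMatrix kept(n_keep, keep.size());
  std::vector<double> th_sum(p, 0.0), th_sumsq(p, 0.0);

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < p; ++j) {
      const bool inU = j >= u_off;
      const int ju = j - u_off;
      const double ad = inU ? adiag[ju] : 0.0;
      const double cjj = wdiag[j] + alpha * ad;
      if (cjj <= 0.0)
        stop("non-positive full-conditional precision at parameter %d", j + 1);
      double num = Wty[j] - v1[j] + cjj * theta[j];
      if (inU) num -= alpha * v2[ju];
      const double mean = num / cjj;
      const double sdv = std::sqrt(se2 / cjj);
      const double nv = mean + norm_rand() * sdv;
      const double delta = nv - theta[j];
      if (delta != 0.0) {
        for (int k = Wp[j]; k < Wp[j + 1]; ++k) v1[Wi[k]] += Wx[k] * delta;
        if (inU)
          for (int k = Ap[ju]; k < Ap[ju + 1]; ++k)
            v2[Ai[k]] += Ax[k] * delta;
        theta[j] = nv;
      }
    }
    if (fix_su2 <= 0.0) {
      double ssu = 0.0;
      for (int j = 0; j < q; ++j) ssu += theta[u_off + j] * v2[j];
      if (ssu < 0.0) ssu = 0.0;
      su2 = (nu_u * S2u + ssu) / R::rchisq(nu_u + q);
    }
    if (fix_se2 <= 0.0) {
      double sse = yty + dotv(theta, v1);
      for (int j = 0; j < p; ++j) sse -= 2.0 * theta[j] * Wty[j];
      if (sse < 0.0) sse = 0.0;
      se2 = (nu_e * S2e + sse) / R::rchisq(nu_e + n_obs);
    }
    alpha = se2 / su2;

    if (refresh > 0 && (it + 1) % refresh == 0) {
      // exact recomputation of v1, v2 to cancel incremental round-off
      std::fill(v1.begin(), v1.end(), 0.0);
      for (int j = 0; j < p; ++j) {
        const double tj = theta[j];
        if (tj == 0.0) continue;
        for (int k = Wp[j]; k < Wp[j + 1]; ++k) v1[Wi[k]] += Wx[k] * tj;
      }
      std::fill(v2.begin(), v2.end(), 0.0);
      for (int j = 0; j < q; ++j) {
        const double tj = theta[u_off + j];
        if (tj == 0.0) continue;
        for (int k = Ap[j]; k < Ap[j + 1]; ++k) v2[Ai[k]] += Ax[k] * tj;
      }
    }

    if (it >= burn_in) {
      const int r = it - burn_in;
      su_chain[r] = su2;
      se_chain[r] = se2;
      for (int m = 0; m < keep.size(); ++m) kept(r, m) = theta[keep[m]];
      for (int j = 0; j < p; ++j) {
        th_sum[j] += theta[j];
        th_sumsq[j] += theta[j] * theta[j];
      }
    }
  }

  NumericVector tmean(p), tsd(p);
  for (int j = 0; j < p; ++j) {
    tmean[j] = th_sum[j] / n_keep;
    double v = th_sumsq[j] / n_keep - tmean[j] * tmean[j];
    tsd[j] = v > 0.0 ? std::sqrt(v) : 0.0;
  }
  return List::create(_["theta_mean"] = tmean, _["theta_sd"] = tsd,
                      _["sigma2_u"] = su_chain, _["sigma2_e"] = se_chain,
                      _["kept"] = kept);
}
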