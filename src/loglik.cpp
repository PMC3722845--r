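#include <Rcpp.h>
using namespace Rcpp;

// Row-wise multinomial-logit log-likelihood: sum_i eta(i, y_i) - logsumexp(eta_i).
// eta has one column per level (column 0 is the reference, usually all zero);
// y is 1-based. Max-subtraction guards against overflow.

static inline double row_ll(const NumericMatrix& eta, int i, int yi) {
  const int L = eta.ncol();
  double m = eta(i, 0);
  for (int k = 1; k < L; ++k) if (eta(i, k) > m) m = eta(i, k);
  double s = 0.0;
  for (int k = 0; k < L; ++k) s += std::exp(eta(i, k) - m);
  return eta(i, yi - 1) - m - std::log(s);
}

// [[Rcpp::export]]
double cpp_loglik(NumericMatrix eta, IntegerVector y) {
  const int n = eta.nrow();
  if (y.size() != n) stop("eta and y lengths differ");
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += row_ll(eta, i, y[i]);
  return tot;
}

static inline double row_ll_upd(const NumericMatrix& eta, int i, int yi,
                                int jcol, const NumericVector& newcol) {
  const int L = eta.ncol();
  double m = (jcol == 0) ? newcol[i] : eta(i, 0);
  for (int k = 1; k < L; ++k) {
    double v = (k == jcol) ? newcol[i] : eta(i, k);
    if (v > m) m = v;
  }
  double s = 0.0;
  for (int k = 0; k < L; ++k)
    s += std::exp(((k == jcol) ? newcol[i] : eta(i, k)) - m);
  double num = (yi - 1 == jcol) ? newcol[i] : eta(i, yi - 1);
  return num - m - std::log(s);
}

// Log-likelihood with column jcol (1-based) of eta replaced by newcol,
// without materialising the modified matrix.
// [[Rcpp::export]]
double cpp_loglik_upd(NumericMatrix eta, IntegerVector y, int jcol,
                      NumericVector newcol) {
  const int n = eta.nrow();
  if (y.size() != n || newcol.size() != n) stop("length mismatch");
  const int jc = jcol - 1;
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += row_ll_upd(eta, i, y[i], jc, newcol);
  return tot;
}

// Per-group variant of cpp_loglik_upd.
// [[Rcpp::export]]
NumericVector cpp_loglik_group_upd(NumericMatrix eta, IntegerVector y,
                                   int jcol, NumericVector newcol,
                                   IntegerVector g, int ngroups) {
  const int n = eta.nrow();
  if (y.size() != n || newcol.size() != n || g.size() != n)
    stop("length mismatch");
  const int jc = jcol - 1;
  NumericVector out(ngroups);
  for (int i = 0; i < n; ++i) out[g[i] - 1] += row_ll_upd(eta, i, y[i], jc, newcol);
  return out;
}

// Element-wise adaptive random-walk Metropolis sweep over one coefficient
// block (beta over X, or gamma over Z). For each free level j and each
// column k of C, proposes coef(k,j) + eps and accepts on the multinomial
// log-likelihood plus a N(0, prior_var) prior. Row log-likelihoods and the
// row-wise sum of exp(eta) are cached so a proposal only touches rows where
// C(i,k) != 0 (and, via `rows`, only the wave slice a time-varying effect
// applies to). eta, coef and ls (log proposal scales) are updated IN PLACE;
// callers must own these objects uniquely. Uses R's RNG (norm_rand /
// unif_rand), so chains are reproducible from set.seed(). Returns the
// number of accepted proposals.
// [[Rcpp::export]]
int cpp_sweep_block(NumericMatrix eta, IntegerVector y, NumericMatrix C,
                    NumericMatrix coef, NumericMatrix ls, IntegerVector rows,
                    double lw, double prior_var, double gain, double target) {
  const int n = eta.nrow(), L = eta.ncol();
  const int p = coef.nrow(), K = coef.ncol();
  if (C.nrow() != n || y.size() != n) stop("dimension mismatch");
  if (K != L - 1) stop("coef must have L-1 columns");
  const bool use_ll = lw > 0.0;

  std::vector<double> S(n), rll(n);
  if (use_ll) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < L; ++k) s += std::exp(eta(i, k));
      S[i] = s;
      rll[i] = eta(i, y[i] - 1) - std::log(s);
    }
  }
  const int nr = rows.size();
  std::vector<int> touched; touched.reserve(nr > 0 ? nr : n);
  std::vector<double> new_eta, new_S, new_rll;
  new_eta.reserve(n); new_S.reserve(n); new_rll.reserve(n);
  int accepted = 0;

  for (int j = 0; j < K; ++j) {
    const int ej = j + 1;
    for (int k = 0; k < p; ++k) {
      const double eps = norm_rand() * std::exp(ls(k, j));
      double dll = 0.0;
      touched.clear(); new_eta.clear(); new_S.clear(); new_rll.clear();
      if (use_ll) {
        const int m = (nr > 0) ? nr : n;
        for (int r = 0; r < m; ++r) {
          const int i = (nr > 0) ? rows[r] : r;
          const double c = C(i, k);
          if (c == 0.0) continue;
          const double old = eta(i, ej);
          const double nev = old + c * eps;
          const double Snew = S[i] - std::exp(old) + std::exp(nev);
          const double num = (y[i] - 1 == ej) ? nev : eta(i, y[i] - 1);
          const double lnew = num - std::log(Snew);
          dll += lnew - rll[i];
          touched.push_back(i);
          new_eta.push_back(nev); new_S.push_back(Snew); new_rll.push_back(lnew);
        }
      }
      const double b_old = coef(k, j), b_new = b_old + eps;
      const double logr = lw * dll +
        (b_old * b_old - b_new * b_new) / (2.0 * prior_var);
      bool acc = R_finite(logr) && std::log(unif_rand()) < logr;
      if (acc) {
        coef(k, j) = b_new;
        for (size_t t = 0; t < touched.size(); ++t) {
          const int i = touched[t];
          eta(i, ej) = new_eta[t]; S[i] = new_S[t]; rll[i] = new_rll[t];
        }
        ++accepted;
      }
      if (gain > 0.0) ls(k, j) += gain * ((acc ? 1.0 : 0.0) - target);
    }
  }
  return accepted;
}

// Marginal deviance: -2 * sum_i log( (1/M) sum_m prod_r P(y_r | eta0_r + sd * Z_m) )
// where r runs over the used rows of patient i and the random intercepts are
// integrated out by Monte Carlo over the M rows of Zm (standard normals,
// shared across patients and parameter draws as common random numbers).
// eta0 holds the fixed-effect linear predictor (column 1 the reference).
// [[Rcpp::export]]
double cpp_marginal_dev(NumericMatrix eta0, IntegerVector y, IntegerVector pat,
                        int N, NumericVector sd_k, NumericMatrix Zm,
                        LogicalVector use_row) {
  const int n = eta0.nrow(), L = eta0.ncol(), M = Zm.nrow(), K = Zm.ncol();
  if (K != L - 1) stop("Zm must have L-1 columns");
  std::vector<double> ll(static_cast<size_t>(N) * M, 0.0);
  std::vector<bool> seen(N, false);
  std::vector<double> e(L);
  for (int r = 0; r < n; ++r) {
    if (!use_row[r]) continue;
    const int i = pat[r] - 1;
    seen[i] = true;
    for (int m = 0; m < M; ++m) {
      double mx = eta0(r, 0);
      e[0] = eta0(r, 0);
      for (int k = 1; k < L; ++k) {
        e[k] = eta0(r, k) + sd_k[k - 1] * Zm(m, k - 1);
        if (e[k] > mx) mx = e[k];
      }
      double s = 0.0;
      for (int k = 0; k < L; ++k) s += std::exp(e[k] - mx);
      ll[static_cast<size_t>(i) * M + m] += e[y[r] - 1] - mx - std::log(s);
    }
  }
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    if (!seen[i]) continue;
    double mx = ll[static_cast<size_t>(i) * M];
    for (int m = 1; m < M; ++m)
      if (ll[static_cast<size_t>(i) * M + m] > mx) mx = ll[static_cast<size_t>(i) * M + m];
    double s = 0.0;
    for (int m = 0; m < M; ++m) s += std::exp(ll[static_cast<size_t>(i) * M + m] - mx);
    tot += mx + std::log(s / M);
  }
  return -2.0 * tot;
}

// Per-group log-likelihood sums; g is a 1-based group index of length n.
// [[Rcpp::export]]
NumericVector cpp_loglik_group(NumericMatrix eta, IntegerVector y,
                               IntegerVector g, int ngroups) {
  const int n = eta.nrow();
  if (y.size() != n || g.size() != n) stop("length mismatch");
  NumericVector out(ngroups);
  for (int i = 0; i < n; ++i) out[g[i] - 1] += row_ll(eta, i, y[i]);
  return out;
}
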