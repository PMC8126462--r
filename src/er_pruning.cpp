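#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-state equal-rates (ER) pruning machinery.
//
// Trees arrive as flat postorder edge arrays (0-based node indices, tips
// 0..ntip-1, edges ordered children-before-parents). Tip states are coded
// 0 = absent, 1 = present, -1 = missing (partial likelihood (1,1)).

static inline void trans(double q, double t, double &psame, double &pdiff) {
  double ex = std::exp(-2.0 * q * t);
  psame = 0.5 * (1.0 + ex);
  pdiff = 0.5 * (1.0 - ex);
}

// Postorder pruning pass: fills root partials (out[0], out[1]) and returns
// the accumulated log scaling factor.
static double root_partials(const IntegerVector &parent,
                            const IntegerVector &child,
                            const NumericVector &len, int nnodes, int root,
                            int ntip, const std::vector<int> &state, double q,
                            double *out) {
  std::vector<double> L0(nnodes, 1.0), L1(nnodes, 1.0);
  for (int i = 0; i < ntip; ++i) {
    if (state[i] == 0) {
      L1[i] = 0.0;
    } else if (state[i] == 1) {
      L0[i] = 0.0;
    } // missing: (1,1)
  }
  double logscale = 0.0;
  int ne = parent.size();
  for (int e = 0; e < ne; ++e) {
    int p = parent[e], c = child[e];
    double ps, pd;
    trans(q, len[e], ps, pd);
    double v0 = ps * L0[c] + pd * L1[c];
    double v1 = pd * L0[c] + ps * L1[c];
    L0[p] *= v0;
    L1[p] *= v1;
    double m = (L0[p] > L1[p]) ? L0[p] : L1[p];
    if (m > 0.0 && m < 1e-200) {
      L0[p] /= m;
      L1[p] /= m;
      logscale += std::log(m);
    }
  }
  out[0] = L0[root];
  out[1] = L1[root];
  return logscale;
}

static double uncorrected_loglik(const IntegerVector &parent,
                                 const IntegerVector &child,
                                 const NumericVector &len, int nnodes,
                                 int root, int ntip,
                                 const std::vector<int> &state, double q,
                                 double pi0, double pi1) {
  double out[2];
  double ls = root_partials(parent, child, len, nnodes, root, ntip, state, q,
                            out);
  double lik = pi0 * out[0] + pi1 * out[1];
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + ls;
}

// Probability of the excluded pattern(s) under the ascertainment variant:
// asc = 0 none, 1 condition on not-all-observed-absent, 2 condition on
// variable (excludes all-absent and all-present among observed tips).
static double excluded_prob(const IntegerVector &parent,
                            const IntegerVector &child,
                            const NumericVector &len, int nnodes, int root,
                            int ntip, const std::vector<int> &state, double q,
                            double pi0, double pi1, int asc) {
  if (asc == 0) return 0.0;
  std::vector<int> s(state);
  for (int i = 0; i < ntip; ++i)
    if (s[i] != -1) s[i] = 0;
  double p = std::exp(uncorrected_loglik(parent, child, len, nnodes, root,
                                         ntip, s, q, pi0, pi1));
  if (asc == 2) {
    for (int i = 0; i < ntip; ++i)
      if (s[i] != -1) s[i] = 1;
    p += std::exp(uncorrected_loglik(parent, child, len, nnodes, root, ntip,
                                     s, q, pi0, pi1));
  }
  return p;
}

static double corrected_loglik(const IntegerVector &parent,
                               const IntegerVector &child,
                               const NumericVector &len, int nnodes, int root,
                               int ntip, const std::vector<int> &state,
                               double q, double pi0, double pi1, int asc) {
  double ll = uncorrected_loglik(parent, child, len, nnodes, root, ntip,
                                 state, q, pi0, pi1);
  if (asc == 0) return ll;
  double pex = excluded_prob(parent, child, len, nnodes, root, ntip, state, q,
                             pi0, pi1, asc);
  if (pex >= 1.0) return R_NegInf;
  return ll - std::log1p(-pex);
}

static std::vector<int> as_state(const IntegerVector &state) {
  std::vector<int> s(state.size());
  for (int i = 0; i < state.size(); ++i)
    s[i] = (state[i] == NA_INTEGER) ? -1 : state[i];
  return s;
}

// [[Rcpp::export(name = ".er_loglik_cpp")]]
double er_loglik_cpp(IntegerVector parent, IntegerVector child,
                     NumericVector len, int nnodes, int root, int ntip,
                     IntegerVector state, double q, double pi0, double pi1,
                     int asc) {
  std::vector<int> s = as_state(state);
  return corrected_loglik(parent, child, len, nnodes, root, ntip, s, q, pi0,
                          pi1, asc);
}

// [[Rcpp::export(name = ".er_root_partials_cpp")]]
NumericVector er_root_partials_cpp(IntegerVector parent, IntegerVector child,
                                   NumericVector len, int nnodes, int root,
                                   int ntip, IntegerVector state, double q) {
  std::vector<int> s = as_state(state);
  double out[2];
  double ls = root_partials(parent, child, len, nnodes, root, ntip, s, q, out);
  return NumericVector::create(out[0], out[1], ls);
}

// [[Rcpp::export(name = ".er_excluded_prob_cpp")]]
double er_excluded_prob_cpp(IntegerVector parent, IntegerVector child,
                            NumericVector len, int nnodes, int root, int ntip,
                            IntegerVector state, double q, double pi0,
                            double pi1, int asc) {
  std::vector<int> s = as_state(state);
  return excluded_prob(parent, child, len, nnodes, root, ntip, s, q, pi0, pi1,
                       asc);
}

struct FitResult {
  double logq;
  double ll;
};

// Golden-section maximization of the (corrected) log-likelihood over log q.
static FitResult fit_logq(const IntegerVector &parent,
                          const IntegerVector &child, const NumericVector &len,
                          int nnodes, int root, int ntip,
                          const std::vector<int> &state, double pi0,
                          double pi1, int asc, double lo, double hi,
                          double tol) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = corrected_loglik(parent, child, len, nnodes, root, ntip, state,
                               std::exp(c), pi0, pi1, asc);
  double fd = corrected_loglik(parent, child, len, nnodes, root, ntip, state,
                               std::exp(d), pi0, pi1, asc);
  while (b - a > tol) {
    if (fc > fd) {
      b = d;
      d = c;
      fd = fc;
      c = b - gr * (b - a);
      fc = corrected_loglik(parent, child, len, nnodes, root, ntip, state,
                            std::exp(c), pi0, pi1, asc);
    } else {
      a = c;
      c = d;
      fc = fd;
      d = a + gr * (b - a);
      fd = corrected_loglik(parent, child, len, nnodes, root, ntip, state,
                            std::exp(d), pi0, pi1, asc);
    }
  }
  FitResult r;
  r.logq = 0.5 * (a + b);
  r.ll = corrected_loglik(parent, child, len, nnodes, root, ntip, state,
                          std::exp(r.logq), pi0, pi1, asc);
  // boundary wins if better: keeps the fit honest for monotone profiles
  double fl = corrected_loglik(parent, child, len, nnodes, root, ntip, state,
                               std::exp(lo), pi0, pi1, asc);
  double fh = corrected_loglik(parent, child, len, nnodes, root, ntip, state,
                               std::exp(hi), pi0, pi1, asc);
  if (fl > r.ll) {
    r.logq = lo;
    r.ll = fl;
  }
  if (fh > r.ll) {
    r.logq = hi;
    r.ll = fh;
  }
  return r;
}

// [[Rcpp::export(name = ".er_fit_character_cpp")]]
NumericVector er_fit_character_cpp(IntegerVector parent, IntegerVector child,
                                   NumericVector len, int nnodes, int root,
                                   int ntip, IntegerVector state, double pi0,
                                   double pi1, int asc, double loglo,
                                   double loghi, double tol) {
  std::vector<int> s = as_state(state);
  FitResult r = fit_logq(parent, child, len, nnodes, root, ntip, s, pi0, pi1,
                         asc, loglo, loghi, tol);
  double q = std::exp(r.logq);
  double out[2];
  double ls = root_partials(parent, child, len, nnodes, root, ntip, s, q, out);
  (void)ls; // scaling cancels in the ratio
  double denom = pi0 * out[0] + pi1 * out[1];
  double rootp1 = (denom > 0.0) ? pi1 * out[1] / denom : NA_REAL;
  return NumericVector::create(q, r.ll, rootp1);
}

// Fit q and compute the marginal root state for one character on every tree
// of a sample. `trees` is a list of lists with elements parent, child, len,
// nnodes, root, tipmap (0-based master index per tree tip). `state` is in
// master tip order. Returns an ntree x 3 matrix (qhat, loglik, rootp1).
// [[Rcpp::export(name = ".er_ase_sample_cpp")]]
NumericMatrix er_ase_sample_cpp(List trees, IntegerVector state, double pi0,
                                double pi1, int asc, double loglo,
                                double loghi, double tol) {
  int ntree = trees.size();
  NumericMatrix out(ntree, 3);
  for (int k = 0; k < ntree; ++k) {
    List tr = trees[k];
    IntegerVector parent = tr["parent"], child = tr["child"],
                  tipmap = tr["tipmap"];
    NumericVector len = tr["len"];
    int nnodes = tr["nnodes"], root = tr["root"];
    int ntip = tipmap.size();
    std::vector<int> s(ntip);
    for (int i = 0; i < ntip; ++i) {
      int v = state[tipmap[i]];
      s[i] = (v == NA_INTEGER) ? -1 : v;
    }
    FitResult r = fit_logq(parent, child, len, nnodes, root, ntip, s, pi0,
                           pi1, asc, loglo, loghi, tol);
    double q = std::exp(r.logq);
    double rp[2];
    root_partials(parent, child, len, nnodes, root, ntip, s, q, rp);
    double denom = pi0 * rp[0] + pi1 * rp[1];
    out(k, 0) = q;
    out(k, 1) = r.ll;
    out(k, 2) = (denom > 0.0) ? pi1 * rp[1] / denom : NA_REAL;
  }
  return out;
}

// Summed (corrected) log-likelihood of many characters sharing one q on one
// tree; states is an ntip x nchar matrix in the tree's own tip order.
// [[Rcpp::export(name = ".er_pooled_loglik_cpp")]]
double er_pooled_loglik_cpp(IntegerVector parent, IntegerVector child,
                            NumericVector len, int nnodes, int root, int ntip,
                            IntegerMatrix states, double q, double pi0,
                            double pi1, int asc) {
  double tot = 0.0;
  for (int j = 0; j < states.ncol(); ++j) {
    std::vector<int> s(ntip);
    for (int i = 0; i < ntip; ++i) {
      int v = states(i, j);
      s[i] = (v == NA_INTEGER) ? -1 : v;
    }
    tot += corrected_loglik(parent, child, len, nnodes, root, ntip, s, q, pi0,
                            pi1, asc);
  }
  return tot;
}
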