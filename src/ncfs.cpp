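#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Packed upper-triangle order: index runs over (i, j) with i < j,
// i outermost. Pairwise weighted L1 distance accumulated per gene so the
// cost scales with the active (nonzero-weight) gene set.
static void pairwise_tri(const NumericMatrix& X, const NumericVector& w,
                         std::vector<double>& tri) {
  const int n = X.nrow(), p = X.ncol();
  std::fill(tri.begin(), tri.end(), 0.0);
  for (int l = 0; l < p; ++l) {
    const double wl2 = w[l] * w[l];
    if (wl2 == 0.0) continue;
    const double* xl = &X(0, l);
    std::size_t idx = 0;
    for (int i = 0; i < n; ++i) {
      const double xi = xl[i];
      for (int j = i + 1; j < n; ++j, ++idx)
        tri[idx] += wl2 * std::fabs(xi - xl[j]);
    }
  }
}

// [[Rcpp::export(".ncfsPairwiseDist")]]
NumericMatrix ncfs_pairwise_dist(const NumericMatrix& X,
                                 const NumericVector& w) {
  if (w.size() != X.ncol())
    stop("length(w) must equal ncol(X)");
  const int n = X.nrow();
  std::vector<double> tri((std::size_t)n * (n - 1) / 2);
  pairwise_tri(X, w, tri);
  NumericMatrix D(n, n);
  std::size_t idx = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j, ++idx)
      D(i, j) = D(j, i) = tri[idx];
  return D;
}

// Reference-point probabilities, per-cell leave-one-out accuracy, the
// regularized objective and (optionally) its analytic gradient.
//
//   p_ij = exp(-D_ij/sigma) / sum_{k != i} exp(-D_ik/sigma),  p_ii = 0
//   p_i  = sum_j y_ij p_ij,   xi(w) = sum_i p_i - lambda sum_l w_l^2
//   d xi/d w_l = 2 w_l [ (1/sigma) sum_ij p_ij (p_i - y_ij) |x_il-x_jl|
//                        - lambda ]
//
// Rows are normalized after subtracting the row minimum of D (log-sum-exp
// shift), which leaves p_ij unchanged but avoids kernel underflow in high
// dimension. A row whose kernels are all non-finite falls back to uniform
// off-diagonal weights; the count of such rows is returned.
// [[Rcpp::export(".ncfsObjGrad")]]
List ncfs_obj_grad(const NumericMatrix& X, const IntegerVector& y,
                   const NumericVector& w, double sigma, double lambda,
                   bool wantGrad, bool wantProbs) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (w.size() != p) stop("length(w) must equal ncol(X)");
  if (!(sigma > 0)) stop("sigma must be > 0");
  if (n < 2) stop("need at least 2 cells");

  std::vector<double> tri((std::size_t)n * (n - 1) / 2);
  pairwise_tri(X, w, tri);

  NumericMatrix D(n, n), P(n, n);
  {
    std::size_t idx = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++idx)
        D(i, j) = D(j, i) = tri[idx];
  }

  NumericVector acc(n);
  int nUnderflow = 0;
  for (int i = 0; i < n; ++i) {
    double mi = std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j)
      if (j != i && D(i, j) < mi) mi = D(i, j);
    double S = 0.0;
    bool ok = R_FINITE(mi);
    if (ok) {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double e = std::exp(-(D(i, j) - mi) / sigma);
        P(i, j) = e;
        S += e;
      }
      ok = R_FINITE(S) && S > 0.0;
    }
    if (!ok) {
      ++nUnderflow;
      for (int j = 0; j < n; ++j) P(i, j) = (j == i) ? 0.0 : 1.0 / (n - 1);
    } else {
      for (int j = 0; j < n; ++j) P(i, j) /= S;
    }
    double pi = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i && y[j] == y[i]) pi += P(i, j);
    acc[i] = pi;
  }

  double penalty = 0.0;
  for (int l = 0; l < p; ++l) penalty += w[l] * w[l];
  double obj = -lambda * penalty;
  for (int i = 0; i < n; ++i) obj += acc[i];

  List out = List::create(Named("objective") = obj,
                          Named("accuracy") = acc,
                          Named("nUnderflow") = nUnderflow);
  if (wantGrad) {
    // symmetrized M_ij = p_ij (p_i - y_ij), packed like tri so the
    // per-gene reduction walks two contiguous arrays
    std::vector<double>& S2 = tri;  // reuse buffer
    std::size_t idx = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++idx) {
        const double yij = (y[j] == y[i]) ? 1.0 : 0.0;
        S2[idx] = P(i, j) * (acc[i] - yij) + P(j, i) * (acc[j] - yij);
      }
    NumericVector g(p);
    for (int l = 0; l < p; ++l) {
      if (w[l] == 0.0) { g[l] = 0.0; continue; }
      const double* xl = &X(0, l);
      double s = 0.0;
      idx = 0;
      for (int i = 0; i < n; ++i) {
        const double xi = xl[i];
        for (int j = i + 1; j < n; ++j, ++idx)
          s += S2[idx] * std::fabs(xi - xl[j]);
      }
      g[l] = 2.0 * w[l] * (s / sigma - lambda);
    }
    out["gradient"] = g;
  }
  if (wantProbs) out["P"] = P;
  return out;
}
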