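#include <Rcpp.h>
using namespace Rcpp;

// Sparse-aware sufficient statistics for the Gamma-Poisson topic model.
//
// For every stored (i, j, y) triplet the multinomial responsibilities
// z_k = softmax_k(Elog_beta[i,k] + Elog_theta[j,k]) are formed with
// max-subtraction and immediately folded into the count-weighted sums
// S_beta[i,k] += y z_k and S_theta[j,k] += y z_k; the D x L x K tensor is
// never materialized. The data part of the evidence lower bound simplifies
// to sum_k z_k (w_k - log z_k) = logsumexp(w), accumulated as y * lse.
//
// i, j are 0-based and must index rows of elog_beta / elog_theta.
// [[Rcpp::export(name = ".aux_stats_sparse")]]
List aux_stats_sparse(const IntegerVector& i, const IntegerVector& j,
                      const NumericVector& y,
                      const NumericMatrix& elog_beta,
                      const NumericMatrix& elog_theta) {
  const int D = elog_beta.nrow();
  const int L = elog_theta.nrow();
  const int K = elog_beta.ncol();
  if (elog_theta.ncol() != K) stop("topic dimensions disagree");
  const R_xlen_t nnz = y.size();
  if (i.size() != nnz || j.size() != nnz) stop("triplet lengths disagree");

  NumericMatrix s_beta(D, K), s_theta(L, K);
  std::vector<double> w(K);
  double loglik = 0.0;

  for (R_xlen_t m = 0; m < nnz; ++m) {
    const int gi = i[m], cj = j[m];
    if (gi < 0 || gi >= D || cj < 0 || cj >= L) stop("triplet index out of range");
    const double ym = y[m];
    double wmax = R_NegInf;
    for (int k = 0; k < K; ++k) {
      const double wk = elog_beta(gi, k) + elog_theta(cj, k);
      if (!R_finite(wk)) stop("non-finite log-weight at stored entry %td", m + 1);
      w[k] = wk;
      if (wk > wmax) wmax = wk;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      w[k] = std::exp(w[k] - wmax);
      s += w[k];
    }
    loglik += ym * (std::log(s) + wmax);
    for (int k = 0; k < K; ++k) {
      const double yz = ym * (w[k] / s);
      s_beta(gi, k) += yz;
      s_theta(cj, k) += yz;
    }
  }

  return List::create(_["s_beta"] = s_beta, _["s_theta"] = s_theta,
                      _["loglik"] = loglik);
}
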