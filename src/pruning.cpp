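#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Felsenstein pruning log-likelihood for one partition.
//
// Mixture over k discrete-gamma categories plus an invariant-sites class:
//   L(site) = p_inv * sum_x pi_x * const_x(site)
//           + (1 - p_inv)/k * sum_c L_c(site)
// Transition matrices come from the cached spectral decomposition of the
// reversible generator: P(t) = A diag(exp(lambda * t)) B.
//
// tip_part: 4 x npat x ntip array of tip conditional likelihoods.
// const_part: 4 x npat array, const_x = prod_tips tip_part[x] (zero-rate
//   likelihood kernel for the invariant class).
// edge_child / edge_parent: postorder edge lists (children before parents),
//   1-based node ids; tips are 1..ntip, internals ntip+1..nnode.
// dist: expected substitutions per site per edge (indexed like edge_child).
// Per-pattern log scalers guard against underflow (rescale when the largest
// partial drops below 1e-100).
// [[Rcpp::export]]
double partition_loglik_cpp(NumericMatrix A, NumericVector lambda,
                            NumericMatrix B, NumericVector dist,
                            IntegerVector edge_child, IntegerVector edge_parent,
                            NumericVector tip_part, NumericVector const_part,
                            NumericVector pat_weight, NumericVector pi,
                            NumericVector cat_rates, double p_inv,
                            int ntip, int nnode) {
  const int npat = pat_weight.size();
  const int ncat = cat_rates.size();
  const int nedge = edge_child.size();
  const double mix = (1.0 - p_inv) / ncat;

  // per-pattern per-category log site likelihoods, combined by log-sum-exp
  std::vector<double> cat_loglik(static_cast<size_t>(npat) * ncat);

  // partials for internal nodes only; tip conditionals are read in place
  const int nint = nnode - ntip;
  std::vector<double> partial(static_cast<size_t>(nint) * npat * 4);
  std::vector<double> scaler(npat);
  double P[16];

  for (int c = 0; c < ncat; ++c) {
    const double r = cat_rates[c];
    std::fill(partial.begin(), partial.end(), 1.0);
    std::fill(scaler.begin(), scaler.end(), 0.0);

    for (int e = 0; e < nedge; ++e) {
      const int ch = edge_child[e] - 1;
      const int pa = edge_parent[e] - 1;
      const double t = dist[e] * r;
      // P = A diag(exp(lambda t)) B
      double el[4];
      for (int i = 0; i < 4; ++i) el[i] = std::exp(lambda[i] * t);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int m = 0; m < 4; ++m) s += A(i, m) * el[m] * B(m, j);
          P[i * 4 + j] = s > 0.0 ? s : 0.0;
        }
      const double *cp = (ch < ntip)
          ? &tip_part[(static_cast<size_t>(ch) * npat) * 4]
          : &partial[(static_cast<size_t>(ch - ntip) * npat) * 4];
      double *pp = &partial[(static_cast<size_t>(pa - ntip) * npat) * 4];
      for (int s = 0; s < npat; ++s) {
        const double *x = cp + static_cast<size_t>(s) * 4;
        double *y = pp + static_cast<size_t>(s) * 4;
        for (int i = 0; i < 4; ++i) {
          double v = P[i * 4 + 0] * x[0] + P[i * 4 + 1] * x[1] +
                     P[i * 4 + 2] * x[2] + P[i * 4 + 3] * x[3];
          y[i] *= v;
        }
      }
      // rescale parent partials when they get small (last visit wins; the
      // parent is complete after its second child edge)
      {
        for (int s = 0; s < npat; ++s) {
          double *y = pp + static_cast<size_t>(s) * 4;
          double mx = y[0];
          for (int i = 1; i < 4; ++i) if (y[i] > mx) mx = y[i];
          if (mx < 1e-100 && mx > 0.0) {
            for (int i = 0; i < 4; ++i) y[i] /= mx;
            scaler[s] += std::log(mx);
          }
        }
      }
    }
    const int root = edge_parent[nedge - 1] - 1;
    double *rp = &partial[(static_cast<size_t>(root - ntip) * npat) * 4];
    for (int s = 0; s < npat; ++s) {
      double lik = 0.0;
      const double *y = rp + static_cast<size_t>(s) * 4;
      for (int i = 0; i < 4; ++i) lik += pi[i] * y[i];
      cat_loglik[static_cast<size_t>(s) * ncat + c] =
          (lik > 0.0 ? std::log(lik) : R_NegInf) + scaler[s];
    }
  }

  double total = 0.0;
  for (int s = 0; s < npat; ++s) {
    // log-sum-exp across categories
    double mx = R_NegInf;
    for (int c = 0; c < ncat; ++c) {
      double v = cat_loglik[static_cast<size_t>(s) * ncat + c];
      if (v > mx) mx = v;
    }
    double log_var = R_NegInf;
    if (R_FINITE(mx)) {
      double acc = 0.0;
      for (int c = 0; c < ncat; ++c)
        acc += std::exp(cat_loglik[static_cast<size_t>(s) * ncat + c] - mx);
      log_var = std::log(mix) + mx + std::log(acc);
    }
    double log_inv = R_NegInf;
    if (p_inv > 0.0) {
      const double *cx = &const_part[static_cast<size_t>(s) * 4];
      double inv_part = 0.0;
      for (int i = 0; i < 4; ++i) inv_part += pi[i] * cx[i];
      if (inv_part > 0.0) log_inv = std::log(p_inv) + std::log(inv_part);
    }
    // combine the two mixture components in log space (deep trees push the
    // variable part far below double range in raw space)
    double site_log;
    if (log_var >= log_inv)
      site_log = R_FINITE(log_var)
          ? log_var + std::log1p(std::exp(log_inv - log_var)) : log_inv;
    else
      site_log = R_FINITE(log_inv)
          ? log_inv + std::log1p(std::exp(log_var - log_inv)) : log_var;
    if (!R_FINITE(site_log)) return R_NegInf;
    total += pat_weight[s] * site_log;
  }
  return total;
}
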