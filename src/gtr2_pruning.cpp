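#include <Rcpp.h>
using namespace Rcpp;

// Per-pattern log-likelihoods for the binary reversible substitution model
// (states 0 = family absent, 1 = present) on a fixed postorder edge list.
//
// The rate matrix is normalised so that branch lengths are expected state
// flips per character: beta = 1 / (2 * pi0 * pi1), giving
//   P_ij(t) = pi_j + (delta_ij - pi_j) * exp(-beta * t).
//
// `edge` is the (2N-3 or 2N-2) x 2 edge matrix of an ape tree in postorder
// (children listed before their parents), 1-based node ids, tips 1..n_tip.
// `tip_states` is n_tip x n_pattern with entries in {0, 1}.  Underflow is
// handled by per-pattern rescaling accumulated in log space.
//
// [[Rcpp::export]]
NumericVector gtr2_site_loglik_cpp(const IntegerMatrix edge,
                                   const NumericVector edge_length,
                                   const int n_tip,
                                   const IntegerMatrix tip_states,
                                   const double pi1) {
  const int n_edge = edge.nrow();
  const int n_pat = tip_states.ncol();
  const double pi0 = 1.0 - pi1;
  const double beta = 1.0 / (2.0 * pi0 * pi1);

  int n_node = 0;
  for (int i = 0; i < n_edge; ++i) {
    if (edge(i, 0) > n_node) n_node = edge(i, 0);
    if (edge(i, 1) > n_node) n_node = edge(i, 1);
  }

  // conditional likelihoods, node-major; tips set from data, internals to 1
  std::vector<double> clv0((size_t)n_node * n_pat), clv1((size_t)n_node * n_pat);
  for (int v = 0; v < n_node; ++v) {
    const bool is_tip = v < n_tip;
    for (int k = 0; k < n_pat; ++k) {
      const size_t idx = (size_t)v * n_pat + k;
      if (is_tip) {
        const int s = tip_states(v, k);
        clv0[idx] = (s == 0) ? 1.0 : 0.0;
        clv1[idx] = (s == 1) ? 1.0 : 0.0;
      } else {
        clv0[idx] = 1.0;
        clv1[idx] = 1.0;
      }
    }
  }

  std::vector<double> logscale(n_pat, 0.0);
  const double tiny = 1e-240, big = 1e240, log_big = std::log(big);

  for (int i = 0; i < n_edge; ++i) {
    const int p = edge(i, 0) - 1;
    const int c = edge(i, 1) - 1;
    const double e = std::exp(-beta * edge_length[i]);
    const double P00 = pi0 + pi1 * e, P01 = pi1 * (1.0 - e);
    const double P10 = pi0 * (1.0 - e), P11 = pi1 + pi0 * e;
    double *c0 = &clv0[(size_t)c * n_pat], *c1 = &clv1[(size_t)c * n_pat];
    double *p0 = &clv0[(size_t)p * n_pat], *p1 = &clv1[(size_t)p * n_pat];
    for (int k = 0; k < n_pat; ++k) {
      const double m0 = P00 * c0[k] + P01 * c1[k];
      const double m1 = P10 * c0[k] + P11 * c1[k];
      p0[k] *= m0;
      p1[k] *= m1;
      if (p0[k] < tiny && p1[k] < tiny) {
        p0[k] *= big;
        p1[k] *= big;
        logscale[k] -= log_big;
      }
    }
  }

  const int root = edge(n_edge - 1, 0) - 1;
  NumericVector out(n_pat);
  const double *r0 = &clv0[(size_t)root * n_pat], *r1 = &clv1[(size_t)root * n_pat];
  for (int k = 0; k < n_pat; ++k)
    out[k] = std::log(pi0 * r0[k] + pi1 * r1[k]) + logscale[k];
  return out;
}
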