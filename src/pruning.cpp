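// Felsenstein pruning for codon site-model mixtures.
//
// The tree arrives as an ape-style postorder edge matrix (1-based node ids,
// tips 1..n_tips, root n_tips+1). Each mixture class supplies the
// eigensystem of its (unscaled) reversible generator; branch lengths are
// pre-multiplied by the class-common rate normalisation on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat prob_matrix(const mat& V, const mat& Vinv, const vec& d,
                       double t) {
  mat P = V * diagmat(exp(d * t)) * Vinv;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  // renormalise rows against rounding drift
  P.each_col() /= sum(P, 1);
  return P;
}

// Per-site log-likelihood for each mixture class.
//
// tips: n_tips x S integer matrix of 0-based codon states, -1 = missing.
// edge: (postorder) E x 2 matrix of 1-based (parent, child).
// Vs/Vinvs/ds: per-class eigensystems; pi: root frequencies (shared).
// Returns an S x K matrix of log site likelihoods.
// [[Rcpp::export]]
arma::mat prune_site_loglik(const arma::imat& tips,
                            const Rcpp::List& Vs,
                            const Rcpp::List& Vinvs,
                            const Rcpp::List& ds,
                            const arma::imat& edge,
                            const arma::vec& edge_len,
                            const arma::vec& pi,
                            const int n_tips) {
  const int S = tips.n_cols;
  const int K = Vs.size();
  const int E = edge.n_rows;
  const int n_state = pi.n_elem;
  int n_node = n_tips;
  for (int e = 0; e < E; ++e) {
    n_node = std::max(n_node, std::max(edge(e, 0), edge(e, 1)));
  }
  const int root = n_tips + 1;

  mat out(S, K);
  for (int k = 0; k < K; ++k) {
    const mat V = Rcpp::as<mat>(Vs[k]);
    const mat Vinv = Rcpp::as<mat>(Vinvs[k]);
    const vec d = Rcpp::as<vec>(ds[k]);

    std::vector<mat> partial(n_node + 1);
    std::vector<bool> seen(n_node + 1, false);
    rowvec logscale(S, fill::zeros);

    for (int e = 0; e < E; ++e) {
      const int parent = edge(e, 0);
      const int child = edge(e, 1);
      mat P = prob_matrix(V, Vinv, d, edge_len(e));

      mat msg;
      if (child <= n_tips) {
        // message from a tip: column of P per observed state
        msg.set_size(n_state, S);
        for (int s = 0; s < S; ++s) {
          const int st = tips(child - 1, s);
          if (st < 0) {
            msg.col(s) = sum(P, 1);  // missing: sum over states = 1
          } else {
            msg.col(s) = P.col(st);
          }
        }
      } else {
        // finalise the internal child's partial, rescale, then propagate
        mat& L = partial[child];
        rowvec m = max(L, 0);
        m.transform([](double x) { return x <= 0.0 ? 1.0 : x; });
        L.each_row() /= m;
        logscale += log(m);
        msg = P * L;
      }

      if (!seen[parent]) {
        partial[parent] = msg;
        seen[parent] = true;
      } else {
        partial[parent] %= msg;
      }
    }

    rowvec site = pi.t() * partial[root];
    for (int s = 0; s < S; ++s) {
      out(s, k) = (site(s) > 0.0 ? std::log(site(s)) : -1e300) + logscale(s);
    }
  }
  return out;
}
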