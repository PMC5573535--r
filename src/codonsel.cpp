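// Numerical core: vectorised Felsenstein pruning over codon-site classes and
// joint (max-product) ancestral reconstruction. Trees arrive in ape's
// postorder edge representation; states are 1..61 sense-codon indices with
// 0/NA meaning missing (gap or ambiguity), which sums over all states.
#include <RcppArmadillo.h>
using namespace Rcpp;

// Per-site log-likelihoods for each rate class.
// edge: n_edge x 2 (parent, child), postorder, 1-based ape node ids.
// U, Ui, d: eigen factorisation of each class's rate matrix Q = U diag(d) Ui.
// tip_states: n_tip x n_sites, 1..n_states, <=0 for missing.
// [[Rcpp::export]]
arma::mat cpp_pruning_logliks(const arma::imat& edge,
                              const arma::vec& edge_len,
                              const int n_tip,
                              const int n_node,
                              const arma::imat& tip_states,
                              const List& U_list,
                              const List& Ui_list,
                              const List& d_list,
                              const arma::vec& pi) {
  const int n_sites = tip_states.n_cols;
  const int n_class = U_list.size();
  const int n_states = pi.n_elem;
  const int n_edge = edge.n_rows;
  arma::mat out(n_sites, n_class);

  for (int k = 0; k < n_class; ++k) {
    arma::mat U = as<arma::mat>(U_list[k]);
    arma::mat Ui = as<arma::mat>(Ui_list[k]);
    arma::vec d = as<arma::vec>(d_list[k]);
    std::vector<arma::mat> partial(n_node + 1);
    std::vector<bool> has(n_node + 1, false);
    arma::rowvec logscale(n_sites, arma::fill::zeros);

    for (int e = 0; e < n_edge; ++e) {
      const int par = edge(e, 0);
      const int ch = edge(e, 1);
      arma::mat P = U * arma::diagmat(arma::exp(d * edge_len[e])) * Ui;
      P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
      arma::mat C(n_states, n_sites);
      if (ch <= n_tip) {
        for (int s = 0; s < n_sites; ++s) {
          const int st = tip_states(ch - 1, s);
          if (st <= 0 || st == NA_INTEGER) {
            C.col(s).ones();
          } else {
            C.col(s) = P.col(st - 1);
          }
        }
      } else {
        C = P * partial[ch];
      }
      if (!has[par]) {
        partial[par] = C;
        has[par] = true;
      } else {
        partial[par] %= C;
      }
      arma::rowvec m = arma::max(partial[par], 0);
      for (int s = 0; s < n_sites; ++s) {
        if (m[s] > 0.0 && m[s] < 1e-120) {
          partial[par].col(s) /= m[s];
          logscale[s] += std::log(m[s]);
        }
      }
    }
    const int root = edge(n_edge - 1, 0);
    arma::rowvec lik = pi.t() * partial[root];
    for (int s = 0; s < n_sites; ++s) {
      out(s, k) = std::log(lik[s]) + logscale[s];
    }
  }
  return out;
}

// Joint maximum-likelihood ancestral states by max-product dynamic
// programming; ties broken toward the lowest state index (arma::index_max
// returns the first maximum). logP_list: per-edge 61x61 log transition
// matrices. Returns n_node x n_sites states (tips keep observed states;
// missing tip states are back-filled from the optimum).
// [[Rcpp::export]]
arma::imat cpp_joint_reconstruct(const arma::imat& edge,
                                 const List& logP_list,
                                 const int n_tip,
                                 const int n_node,
                                 const arma::imat& tip_states,
                                 const arma::vec& log_pi) {
  const int n_sites = tip_states.n_cols;
  const int n_states = log_pi.n_elem;
  const int n_edge = edge.n_rows;

  std::vector<arma::mat> score(n_node + 1);
  std::vector<bool> has(n_node + 1, false);
  std::vector<arma::imat> back(n_edge);

  for (int e = 0; e < n_edge; ++e) {
    const int par = edge(e, 0);
    const int ch = edge(e, 1);
    arma::mat logP = as<arma::mat>(logP_list[e]);
    arma::mat msg(n_states, n_sites);
    arma::imat bk(n_states, n_sites);
    if (ch <= n_tip) {
      arma::vec rowbest(n_states);
      arma::ivec rowarg(n_states);
      for (int i = 0; i < n_states; ++i) {
        rowbest[i] = logP.row(i).max();
        rowarg[i] = (int) logP.row(i).index_max();
      }
      for (int s = 0; s < n_sites; ++s) {
        const int st = tip_states(ch - 1, s);
        if (st <= 0 || st == NA_INTEGER) {
          msg.col(s) = rowbest;
          bk.col(s) = rowarg;
        } else {
          msg.col(s) = logP.col(st - 1);
          bk.col(s).fill(st - 1);
        }
      }
    } else {
      const arma::mat& S = score[ch];
      for (int s = 0; s < n_sites; ++s) {
        for (int i = 0; i < n_states; ++i) {
          double best = -arma::datum::inf;
          int arg = 0;
          for (int j = 0; j < n_states; ++j) {
            const double v = logP(i, j) + S(j, s);
            if (v > best) { best = v; arg = j; }
          }
          msg(i, s) = best;
          bk(i, s) = arg;
        }
      }
    }
    back[e] = bk;
    if (!has[par]) {
      score[par] = msg;
      has[par] = true;
    } else {
      score[par] += msg;
    }
  }

  arma::imat states(n_node, n_sites);
  for (int t = 0; t < n_tip; ++t) {
    for (int s = 0; s < n_sites; ++s) states(t, s) = tip_states(t, s);
  }
  const int root = edge(n_edge - 1, 0);
  for (int s = 0; s < n_sites; ++s) {
    arma::vec v = log_pi + score[root].col(s);
    states(root - 1, s) = (int) v.index_max() + 1;
  }
  // Preorder pass: reverse postorder guarantees the parent state is known.
  for (int e = n_edge - 1; e >= 0; --e) {
    const int par = edge(e, 0);
    const int ch = edge(e, 1);
    for (int s = 0; s < n_sites; ++s) {
      const int pst = states(par - 1, s);
      const int cst = back[e](pst - 1, s) + 1;
      if (ch > n_tip || tip_states(ch - 1, s) <= 0 ||
          tip_states(ch - 1, s) == NA_INTEGER) {
        states(ch - 1, s) = cst;
      }
    }
  }
  return states;
}
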