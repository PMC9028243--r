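#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Transition matrices P(t_e) = A diag(exp(values * t_e)) Ainv for every
// branch of a reversible substitution model, tiny negative round-off
// clamped to zero.
// [[Rcpp::export]]
arma::cube cpp_edge_pmats(const arma::mat& A, const arma::mat& Ainv,
                          const arma::vec& values, const arma::vec& ts) {
  const arma::uword S = A.n_rows, E = ts.n_elem;
  arma::cube P(S, S, E);
  for (arma::uword e = 0; e < E; ++e) {
    arma::mat M = A * arma::diagmat(arma::exp(values * ts[e])) * Ainv;
    M.clamp(0.0, arma::datum::inf);
    P.slice(e) = M;
  }
  return P;
}

// Felsenstein pruning for one set of edge matrices. Tip children with a
// fully observed state use a column gather instead of a matrix product.
static arma::vec prune_one(const arma::ivec& parent, const arma::ivec& child,
                           const std::vector<const arma::cube*>& Ps,
                           const arma::ivec& which_P,
                           const arma::imat& tipstate,
                           const arma::vec& pi, const int n_node) {
  const arma::uword S = Ps[0]->n_rows, E = parent.n_elem;
  const arma::uword N = tipstate.n_rows, M = tipstate.n_cols;
  const arma::uword total = N + (arma::uword)n_node;
  arma::cube L(S, M, total);
  for (arma::uword v = N; v < total; ++v)
    L.slice(v).ones();
  arma::rowvec logscale(M, arma::fill::zeros);
  std::vector<bool> scaled(total, false);
  arma::mat msg(S, M);
  for (arma::uword e = 0; e < E; ++e) {
    arma::uword c = (arma::uword)child[e] - 1;
    arma::uword p = (arma::uword)parent[e] - 1;
    const arma::mat& P = Ps[which_P[e]]->slice(e);
    if (c < N) {
      for (arma::uword m = 0; m < M; ++m) {
        int s = tipstate(c, m);
        if (s > 0) msg.col(m) = P.col(s - 1);
        else       msg.col(m) = arma::sum(P, 1);  // missing: all states
      }
    } else {
      if (!scaled[c]) {
        arma::rowvec mx = arma::max(L.slice(c), 0);
        mx.replace(0.0, 1.0);
        L.slice(c).each_row() /= mx;
        logscale += arma::log(mx);
        scaled[c] = true;
      }
      msg = P * L.slice(c);
    }
    L.slice(p) %= msg;
  }
  arma::uword root = (arma::uword)parent[E - 1] - 1;
  arma::rowvec lik = pi.t() * L.slice(root);
  arma::vec out(M);
  for (arma::uword m = 0; m < M; ++m)
    out[m] = std::log(lik[m]) + logscale[m];
  return out;
}

// Felsenstein pruning over site patterns with per-node rescaling.
//
// parent/child: 1-based ape node ids in postorder edge order (children
// complete before their parent edge is used). P: S x S x E transition
// matrices, rows = parent state, cols = child state. tipstate: Ntip x M
// integer matrix of 1-based states, 0 = missing. pi: root distribution.
// Returns per-pattern log-likelihoods.
// [[Rcpp::export]]
arma::vec cpp_prune_loglik(const arma::ivec& parent, const arma::ivec& child,
                           const arma::cube& P, const arma::imat& tipstate,
                           const arma::vec& pi, const int n_node) {
  std::vector<const arma::cube*> Ps{&P};
  arma::ivec which_P(parent.n_elem, arma::fill::zeros);
  return prune_one(parent, child, Ps, which_P, tipstate, pi, n_node);
}

// Mixture pruning: Plist holds one S x S x E cube per rate/omega regime;
// class_idx (E x nclass, 1-based into Plist) picks the regime used on
// each edge under each site class. Returns an M x nclass matrix of
// per-pattern log-likelihoods.
// [[Rcpp::export]]
arma::mat cpp_prune_multi(const arma::ivec& parent, const arma::ivec& child,
                          const Rcpp::List& Plist, const arma::imat& class_idx,
                          const arma::imat& tipstate, const arma::vec& pi,
                          const int n_node) {
  const arma::uword nclass = class_idx.n_cols;
  std::vector<arma::cube> cubes;
  cubes.reserve(Plist.size());
  for (int i = 0; i < Plist.size(); ++i)
    cubes.push_back(Rcpp::as<arma::cube>(Plist[i]));
  std::vector<const arma::cube*> Ps;
  for (auto& c : cubes) Ps.push_back(&c);
  arma::mat out(tipstate.n_cols, nclass);
  for (arma::uword cl = 0; cl < nclass; ++cl) {
    arma::ivec wp = class_idx.col(cl) - 1;
    out.col(cl) = prune_one(parent, child, Ps, wp, tipstate, pi, n_node);
  }
  return out;
}
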