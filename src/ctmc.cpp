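// Pruning likelihood for binary / paired-binary traits under a CTMC on a
// rooted tree. The 4-state pair model makes calibration experiments
// fit-count heavy, so the inner DP lives here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LNL_SENTINEL = -1e308;

// Closed-form 2-state transition matrix for generator {{-q01,q01},{q10,-q10}}.
static arma::mat p2_closed(double q01, double q10, double t) {
  arma::mat P(2, 2);
  double s = q01 + q10;
  if (s <= 0.0 || t == 0.0) {
    P.eye(2, 2);
    return P;
  }
  double e = std::exp(-s * t);
  double pi0 = q10 / s, pi1 = q01 / s;
  P(0, 0) = pi0 + pi1 * e;
  P(0, 1) = pi1 * (1.0 - e);
  P(1, 0) = pi0 * (1.0 - e);
  P(1, 1) = pi1 + pi0 * e;
  return P;
}

static void clamp_stochastic(arma::mat &P) {
  P.elem(arma::find(P < 0.0)).zeros();
  P.elem(arma::find(P > 1.0)).ones();
}

// Transition matrices for all edge lengths. For k > 2 one eigendecomposition
// is reused across edges; ill-conditioned eigenvector matrices fall back to
// scaling-and-squaring per edge.
static std::vector<arma::mat> edge_probs(const arma::mat &Q,
                                         const arma::vec &lens) {
  const arma::uword k = Q.n_rows;
  const arma::uword E = lens.n_elem;
  std::vector<arma::mat> out(E);
  if (k == 2) {
    for (arma::uword e = 0; e < E; ++e)
      out[e] = p2_closed(Q(0, 1), Q(1, 0), lens(e));
    return out;
  }
  arma::cx_vec eval;
  arma::cx_mat evec;
  bool ok = arma::eig_gen(eval, evec, Q);
  arma::cx_mat evinv;
  if (ok) ok = arma::inv(evinv, evec);
  if (ok) ok = arma::rcond(arma::mat(arma::abs(evec))) > 1e-12;
  if (ok) {
    for (arma::uword e = 0; e < E; ++e) {
      arma::cx_vec d = arma::exp(eval * lens(e));
      arma::mat P = arma::real(evec * arma::diagmat(d) * evinv);
      clamp_stochastic(P);
      out[e] = P;
    }
  } else {
    for (arma::uword e = 0; e < E; ++e) {
      arma::mat P = arma::expmat(Q * lens(e));
      clamp_stochastic(P);
      out[e] = P;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_transition_matrix(const arma::mat &Q, double t) {
  arma::vec lens(1);
  lens(0) = t;
  return edge_probs(Q, lens)[0];
}

// Felsenstein pruning over a rooted (possibly multifurcating) tree.
// edge: E x 2 integer matrix (parent, child), 1-based ape ids, postorder
// (children always appear as child before appearing as parent).
// tip_states: 0-based state index per tip (tips are ids 1..n_tip).
static double tree_loglik_impl(const arma::imat &edge,
                               const arma::vec &edge_len, int n_tip,
                               const arma::ivec &tip_states,
                               const arma::mat &Q,
                               const arma::vec &root_prior) {
  const arma::uword k = Q.n_rows;
  const arma::uword E = edge.n_rows;
  const int n_node = n_tip + static_cast<int>(E) + 1;  // upper bound on ids
  arma::mat L(n_node + 1, k, arma::fill::ones);
  arma::vec lscale(n_node + 1, arma::fill::zeros);
  for (int i = 0; i < n_tip; ++i) {
    L.row(i + 1).zeros();
    L(i + 1, static_cast<arma::uword>(tip_states(i))) = 1.0;
  }
  std::vector<arma::mat> P = edge_probs(Q, edge_len);
  for (arma::uword e = 0; e < E; ++e) {
    const int p = edge(e, 0), c = edge(e, 1);
    arma::rowvec v = L.row(c) * P[e].t();  // v[i] = sum_j P(i->j) L_c(j)
    double m = v.max();
    if (m <= 0.0 || !std::isfinite(m)) return LNL_SENTINEL;
    v /= m;
    L.row(p) %= v;
    lscale(p) += lscale(c) + std::log(m);
  }
  const int root = n_tip + 1;
  double lik = arma::dot(L.row(root), root_prior.t());
  if (lik <= 0.0 || !std::isfinite(lik)) return LNL_SENTINEL;
  return std::log(lik) + lscale(root);
}

// [[Rcpp::export]]
double cpp_tree_loglik(const arma::imat &edge, const arma::vec &edge_len,
                       int n_tip, const arma::ivec &tip_states,
                       const arma::mat &Q, const arma::vec &root_prior) {
  return tree_loglik_impl(edge, edge_len, n_tip, tip_states, Q, root_prior);
}

// Generator from a packed rate vector. model: 1 = single (q01, q10),
// 2 = pair-independent (gain_a, gain_b, loss_a, loss_b),
// 3 = pair-dependent (alpha1, alpha2, beta1, beta2, gamma1, gamma2,
// delta1, delta2). Pair states ordered 00, 01, 10, 11; dual changes 0.
static arma::mat build_generator(const arma::vec &r, int model) {
  if (model == 1) {
    arma::mat Q(2, 2, arma::fill::zeros);
    Q(0, 1) = r(0);
    Q(1, 0) = r(1);
    Q.diag() = -arma::sum(Q, 1);
    return Q;
  }
  double a1, a2, b1, b2, g1, g2, d1, d2;
  if (model == 2) {
    a1 = a2 = r(0); b1 = b2 = r(1); g1 = g2 = r(2); d1 = d2 = r(3);
  } else {
    a1 = r(0); a2 = r(1); b1 = r(2); b2 = r(3);
    g1 = r(4); g2 = r(5); d1 = r(6); d2 = r(7);
  }
  arma::mat Q(4, 4, arma::fill::zeros);
  Q(0, 2) = a1; Q(1, 3) = a2;   // gain A
  Q(0, 1) = b1; Q(2, 3) = b2;   // gain B
  Q(2, 0) = g1; Q(3, 1) = g2;   // loss A
  Q(1, 0) = d1; Q(3, 2) = d2;   // loss B
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// Negative log-likelihood for the optimizer: rates on the natural scale,
// the hot path of fit_model(). Impossible configurations are capped so
// line searches see a large finite penalty.
// [[Rcpp::export]]
double cpp_negll(const arma::vec &rates, int model, const arma::imat &edge,
                 const arma::vec &edge_len, int n_tip,
                 const arma::ivec &tip_states, const arma::vec &root_prior) {
  arma::mat Q = build_generator(rates, model);
  double ll = tree_loglik_impl(edge, edge_len, n_tip, tip_states, Q,
                               root_prior);
  if (ll < -1e10) return 1e10;
  return -ll;
}
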