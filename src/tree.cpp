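#include "tree.h"
#include <cmath>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

CutpointSet cutpoints_from_list(const List& cp) {
  CutpointSet out(cp.size());
  for (int q = 0; q < cp.size(); ++q) {
    NumericVector v = cp[q];
    out[q] = std::vector<double>(v.begin(), v.end());
  }
  return out;
}

Tree tree_from_df(const DataFrame& df) {
  IntegerVector parent = df["parent"], left = df["left"], right = df["right"];
  IntegerVector var = df["var"];
  NumericVector cut = df["cutoff"], mu = df["mu"];
  int n = parent.size();
  Tree tree;
  tree.nodes.resize(n);
  for (int i = 0; i < n; ++i) {
    Node& nd = tree.nodes[i];
    nd.parent = parent[i] - 1;          // 0 encodes "none"
    nd.left = left[i] - 1;
    nd.right = right[i] - 1;
    nd.var = var[i] - 1;
    nd.cut = (nd.var >= 0) ? cut[i] : 0.0;
    nd.mu = (nd.left < 0 && !NumericVector::is_na(mu[i])) ? mu[i] : 0.0;
  }
  return tree;
}

DataFrame tree_to_df(const Tree& tree) {
  int n = tree.nodes.size();
  IntegerVector node(n), parent(n), left(n), right(n), var(n);
  NumericVector cut(n), mu(n);
  for (int i = 0; i < n; ++i) {
    const Node& nd = tree.nodes[i];
    node[i] = i + 1;
    parent[i] = nd.parent + 1;
    left[i] = nd.left + 1;
    right[i] = nd.right + 1;
    var[i] = nd.var + 1;
    cut[i] = (nd.var >= 0) ? nd.cut : NA_REAL;
    mu[i] = (nd.left < 0) ? nd.mu : NA_REAL;
  }
  return DataFrame::create(_["node"] = node, _["parent"] = parent,
                           _["left"] = left, _["right"] = right,
                           _["var"] = var, _["cutoff"] = cut, _["mu"] = mu);
}

// X is column-major with nrow rows; covariate q of row i is X[q*nrow + i].
int route_obs(const Tree& tree, const double* X, int nrow, int i) {
  int node = 0;
  while (!tree.is_leaf(node)) {
    const Node& nd = tree.nodes[node];
    node = (X[(size_t)nd.var * nrow + i] <= nd.cut) ? nd.left : nd.right;
  }
  return node;
}

void eval_tree(const Tree& tree, const double* X, int nrow, double* out) {
  for (int i = 0; i < nrow; ++i)
    out[i] = tree.nodes[route_obs(tree, X, nrow, i)].mu;
}

void route_assign(const Tree& tree, const double* X, int nrow, int* assign) {
  for (int i = 0; i < nrow; ++i)
    assign[i] = route_obs(tree, X, nrow, i);
}

void stats_from_assign(const Tree& tree, const int* assign, int nrow,
                       const double* resid, LeafWork& w) {
  size_t m = tree.nodes.size();
  w.assign.assign(assign, assign + nrow);
  w.n.assign(m, 0);
  w.s.assign(m, 0.0);
  w.s2.assign(m, 0.0);
  for (int i = 0; i < nrow; ++i) {
    int leaf = assign[i];
    ++w.n[leaf];
    w.s[leaf] += resid[i];
    w.s2[leaf] += resid[i] * resid[i];
  }
}

void route_stats(const Tree& tree, const double* X, int nrow,
                 const double* resid, LeafWork& w) {
  size_t m = tree.nodes.size();
  w.assign.resize(nrow);
  w.n.assign(m, 0);
  w.s.assign(m, 0.0);
  w.s2.assign(m, 0.0);
  for (int i = 0; i < nrow; ++i) {
    int leaf = route_obs(tree, X, nrow, i);
    w.assign[i] = leaf;
    ++w.n[leaf];
    w.s[leaf] += resid[i];
    w.s2[leaf] += resid[i] * resid[i];
  }
}

// Marginal likelihood of unit-variance residuals with the leaf means
// integrated out under N(0, sigma_mu^2); an empty leaf contributes 0.
double intloglik_stats(const Tree& tree, const LeafWork& w, double sigma_mu) {
  double v = sigma_mu * sigma_mu, ll = 0.0;
  for (size_t t = 0; t < tree.nodes.size(); ++t) {
    if (!tree.is_leaf(t) || w.n[t] == 0) continue;
    double nt = w.n[t];
    ll += -0.5 * nt * LOG2PI - 0.5 * std::log1p(nt * v) - 0.5 * w.s2[t] +
          0.5 * v * w.s[t] * w.s[t] / (1.0 + nt * v);
  }
  return ll;
}

void draw_leaves_stats(Tree& tree, const LeafWork& w, double sigma_mu) {
  double prec0 = 1.0 / (sigma_mu * sigma_mu);
  for (size_t t = 0; t < tree.nodes.size(); ++t) {
    if (!tree.is_leaf(t)) continue;
    double post_var = 1.0 / (w.n[t] + prec0);
    tree.nodes[t].mu = w.s[t] * post_var + std::sqrt(post_var) * norm_rand();
  }
}

static bool min_leaf_ok(const Tree& tree, const LeafWork& w, int min_leaf) {
  if (min_leaf <= 0) return true;
  for (size_t t = 0; t < tree.nodes.size(); ++t)
    if (tree.is_leaf(t) && w.n[t] < min_leaf) return false;
  return true;
}

static int n_available_vars(const CutpointSet& cuts) {
  int n = 0;
  for (size_t q = 0; q < cuts.size(); ++q) if (!cuts[q].empty()) ++n;
  return n;
}

double tree_log_prior(const Tree& tree, double alpha, double beta,
                      const CutpointSet& cuts) {
  int q_avail = n_available_vars(cuts);
  double lp = 0.0;
  for (size_t i = 0; i < tree.nodes.size(); ++i) {
    double d = tree.depth(i);
    double p_split = alpha * std::pow(1.0 + d, -beta);
    if (tree.is_leaf(i)) {
      lp += std::log1p(-p_split);
    } else {
      lp += std::log(p_split) - std::log((double)q_avail) -
            std::log((double)cuts[tree.nodes[i].var].size());
    }
  }
  return lp;
}

double tree_integrated_loglik(const Tree& tree, const double* X, int nrow,
                              const double* resid, double sigma_mu) {
  LeafWork w;
  route_stats(tree, X, nrow, resid, w);
  return intloglik_stats(tree, w, sigma_mu);
}

static void collect_nodes(const Tree& tree, std::vector<int>& leaves,
                          std::vector<int>& internals, std::vector<int>& nogs) {
  leaves.clear(); internals.clear(); nogs.clear();
  for (size_t i = 0; i < tree.nodes.size(); ++i) {
    if (tree.is_leaf(i)) { leaves.push_back(i); continue; }
    internals.push_back(i);
    if (tree.is_leaf(tree.nodes[i].left) && tree.is_leaf(tree.nodes[i].right))
      nogs.push_back(i);
  }
}

// (parent, child) pairs where both hold decision rules
static void collect_swap_pairs(const Tree& tree,
                               std::vector<std::pair<int, int> >& pairs) {
  pairs.clear();
  for (size_t i = 0; i < tree.nodes.size(); ++i) {
    if (tree.is_leaf(i)) continue;
    int l = tree.nodes[i].left, r = tree.nodes[i].right;
    if (!tree.is_leaf(l)) pairs.push_back(std::make_pair((int)i, l));
    if (!tree.is_leaf(r)) pairs.push_back(std::make_pair((int)i, r));
  }
}

// Probability that move m is selected at tree state `tree`, given the fixed
// per-move weights renormalised over the moves available at that state.
static double move_prob(const Tree& tree, int m, const double* w,
                        const CutpointSet& cuts) {
  std::vector<int> leaves, internals, nogs;
  std::vector<std::pair<int, int> > pairs;
  collect_nodes(tree, leaves, internals, nogs);
  collect_swap_pairs(tree, pairs);
  bool avail[4];
  avail[MOVE_GROW] = n_available_vars(cuts) > 0;
  avail[MOVE_PRUNE] = !nogs.empty();
  avail[MOVE_CHANGE] = !internals.empty();
  avail[MOVE_SWAP] = !pairs.empty();
  double tot = 0.0;
  for (int k = 0; k < 4; ++k) if (avail[k]) tot += w[k];
  if (!avail[m] || tot <= 0.0) return 0.0;
  return w[m] / tot;
}

static int sample_index(int n) { return (int)std::floor(unif_rand() * n) % n; }

// uniform draw over covariates with a non-empty cutpoint set
static int sample_var(const CutpointSet& cuts) {
  int q_avail = n_available_vars(cuts);
  int pick = sample_index(q_avail);
  for (size_t q = 0; q < cuts.size(); ++q) {
    if (cuts[q].empty()) continue;
    if (pick-- == 0) return q;
  }
  return -1;
}

static void remove_two_nodes(Tree& tree, int a, int b) {
  if (a > b) std::swap(a, b);
  tree.nodes.erase(tree.nodes.begin() + b);
  tree.nodes.erase(tree.nodes.begin() + a);
  for (size_t i = 0; i < tree.nodes.size(); ++i) {
    Node& nd = tree.nodes[i];
    int* idx[3] = { &nd.parent, &nd.left, &nd.right };
    for (int k = 0; k < 3; ++k) {
      if (*idx[k] < 0) continue;
      int shift = (*idx[k] > b ? 2 : (*idx[k] > a ? 1 : 0));
      *idx[k] -= shift;
    }
  }
}

void tree_mh_step(Tree& tree, const double* X, int nrow, const double* resid,
                  double sigma_mu, double alpha, double beta,
                  const CutpointSet& cuts, const double* w, int min_leaf,
                  int* move_out, bool* accepted, double* log_alpha,
                  LeafWork& work, LeafWork& scratch, bool work_ready) {
  *accepted = false;
  *log_alpha = R_NegInf;
  *move_out = -1;

  std::vector<int> leaves, internals, nogs;
  std::vector<std::pair<int, int> > pairs;
  collect_nodes(tree, leaves, internals, nogs);
  collect_swap_pairs(tree, pairs);
  int q_avail = n_available_vars(cuts);

  if (!work_ready) route_stats(tree, X, nrow, resid, work);

  bool avail[4] = { q_avail > 0, !nogs.empty(), !internals.empty(),
                    !pairs.empty() };
  double tot = 0.0;
  for (int k = 0; k < 4; ++k) if (avail[k]) tot += w[k];
  if (tot <= 0.0) {  // no structural move possible; Gibbs leaf update only
    draw_leaves_stats(tree, work, sigma_mu);
    return;
  }
  double u = unif_rand() * tot, acc = 0.0;
  int move = -1;
  for (int k = 0; k < 4; ++k) {
    if (!avail[k]) continue;
    acc += w[k];
    if (u <= acc) { move = k; break; }
  }
  if (move < 0) move = MOVE_CHANGE;
  *move_out = move;

  Tree prop = tree;
  double log_qratio = 0.0;

  if (move == MOVE_GROW) {
    int leaf = leaves[sample_index(leaves.size())];
    int var = sample_var(cuts);
    int ci = sample_index(cuts[var].size());
    Node child; child.parent = leaf; child.left = child.right = -1;
    child.var = -1; child.cut = 0.0; child.mu = 0.0;
    prop.nodes.push_back(child);
    prop.nodes.push_back(child);
    Node& nd = prop.nodes[leaf];
    nd.var = var; nd.cut = cuts[var][ci];
    nd.left = prop.nodes.size() - 2;
    nd.right = prop.nodes.size() - 1;
    std::vector<int> pl, pi, pn;
    collect_nodes(prop, pl, pi, pn);
    double fwd = std::log(move_prob(tree, MOVE_GROW, w, cuts)) -
                 std::log((double)leaves.size()) -
                 std::log((double)q_avail) -
                 std::log((double)cuts[var].size());
    double rev = std::log(move_prob(prop, MOVE_PRUNE, w, cuts)) -
                 std::log((double)pn.size());
    log_qratio = rev - fwd;
  } else if (move == MOVE_PRUNE) {
    int nog = nogs[sample_index(nogs.size())];
    int q_removed = prop.nodes[nog].var;
    int c1 = prop.nodes[nog].left, c2 = prop.nodes[nog].right;
    prop.nodes[nog].left = prop.nodes[nog].right = -1;
    prop.nodes[nog].var = -1;
    remove_two_nodes(prop, c1, c2);
    double fwd = std::log(move_prob(tree, MOVE_PRUNE, w, cuts)) -
                 std::log((double)nogs.size());
    double rev = std::log(move_prob(prop, MOVE_GROW, w, cuts)) -
                 std::log((double)prop.n_leaves()) -
                 std::log((double)q_avail) -
                 std::log((double)cuts[q_removed].size());
    log_qratio = rev - fwd;
  } else if (move == MOVE_CHANGE) {
    int node = internals[sample_index(internals.size())];
    int var = sample_var(cuts);
    prop.nodes[node].var = var;
    prop.nodes[node].cut = cuts[var][sample_index(cuts[var].size())];
    log_qratio = 0.0;  // symmetric: same candidate set both directions
  } else {  // MOVE_SWAP
    std::pair<int, int> pr = pairs[sample_index(pairs.size())];
    std::swap(prop.nodes[pr.first].var, prop.nodes[pr.second].var);
    std::swap(prop.nodes[pr.first].cut, prop.nodes[pr.second].cut);
    log_qratio = 0.0;  // symmetric involution
  }

  route_stats(prop, X, nrow, resid, scratch);
  if (min_leaf_ok(prop, scratch, min_leaf)) {
    double la = intloglik_stats(prop, scratch, sigma_mu) -
                intloglik_stats(tree, work, sigma_mu) +
                tree_log_prior(prop, alpha, beta, cuts) -
                tree_log_prior(tree, alpha, beta, cuts) + log_qratio;
    *log_alpha = la;
    if (std::log(unif_rand()) < la) {
      tree = prop;
      std::swap(work, scratch);
      *accepted = true;
    }
  }
  draw_leaves_stats(tree, work, sigma_mu);
}

// One-sided truncated normal draws, stable far into the tail (|mu| ~ 10):
// naive rejection near the bulk, Robert's exponential-envelope rejection in
// the tail.
double rtnorm_one_sided(double mu, int positive) {
  double m = positive ? mu : -mu;
  double a = -m;  // need standard normal z > a
  double z;
  if (a <= 0.45) {
    do { z = norm_rand(); } while (z <= a);
  } else {
    double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (;;) {
      z = a + exp_rand() / lam;
      double rho = std::exp(-0.5 * (z - lam) * (z - lam));
      if (unif_rand() < rho) break;
    }
  }
  double out = m + z;
  return positive ? out : -out;
}
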