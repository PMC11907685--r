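#ifndef GTBART_TREE_H
#define GTBART_TREE_H

#include <Rcpp.h>
#include <vector>

// A binary regression tree stored as a flat node vector (node 0 is the root).
// Interior nodes hold a decision rule {x_var <= cut} (left) vs {x_var > cut}
// (right); leaves hold a scalar parameter mu.
struct Node {
  int parent;   // -1 for root
  int left;     // -1 if leaf
  int right;    // -1 if leaf
  int var;      // 0-based covariate index, -1 if leaf
  double cut;
  double mu;
};

struct Tree {
  std::vector<Node> nodes;

  Tree() {
    Node root;
    root.parent = -1; root.left = -1; root.right = -1;
    root.var = -1; root.cut = 0.0; root.mu = 0.0;
    nodes.push_back(root);
  }

  bool is_leaf(int i) const { return nodes[i].left < 0; }

  int depth(int i) const {
    int d = 0;
    while (nodes[i].parent >= 0) { i = nodes[i].parent; ++d; }
    return d;
  }

  int n_leaves() const {
    int n = 0;
    for (size_t i = 0; i < nodes.size(); ++i) if (is_leaf((int)i)) ++n;
    return n;
  }
};

typedef std::vector<std::vector<double> > CutpointSet;

// Per-observation routing plus per-leaf sufficient statistics of the partial
// residuals; reused across the likelihood evaluation, the minimum-leaf check,
// the conjugate leaf redraw and the fitted-value update so each tree is
// routed only once per Metropolis step.
struct LeafWork {
  std::vector<int> assign;          // leaf node id per observation
  std::vector<int> n;               // per node id
  std::vector<double> s, s2;        // sum / sum of squares per node id
};

// Move codes
enum TreeMove { MOVE_GROW = 0, MOVE_PRUNE = 1, MOVE_CHANGE = 2, MOVE_SWAP = 3 };

CutpointSet cutpoints_from_list(const Rcpp::List& cp);
Tree tree_from_df(const Rcpp::DataFrame& df);
Rcpp::DataFrame tree_to_df(const Tree& tree);

int route_obs(const Tree& tree, const double* X, int nrow, int i);
void eval_tree(const Tree& tree, const double* X, int nrow, double* out);

void route_stats(const Tree& tree, const double* X, int nrow,
                 const double* resid, LeafWork& w);
void route_assign(const Tree& tree, const double* X, int nrow, int* assign);
void stats_from_assign(const Tree& tree, const int* assign, int nrow,
                       const double* resid, LeafWork& w);
double intloglik_stats(const Tree& tree, const LeafWork& w, double sigma_mu);
void draw_leaves_stats(Tree& tree, const LeafWork& w, double sigma_mu);

double tree_log_prior(const Tree& tree, double alpha, double beta,
                      const CutpointSet& cuts);
double tree_integrated_loglik(const Tree& tree, const double* X, int nrow,
                              const double* resid, double sigma_mu);

// One Metropolis-Hastings structural step (GROW/PRUNE/CHANGE/SWAP) followed
// by a conjugate redraw of all leaf values.  On exit `work` holds the
// routing/statistics of the final tree; pass work_ready = true when `work`
// already holds the statistics of the current tree (saves one routing).
// Returns the move attempted (-1 if none was available), whether it was
// accepted, and the pre-truncation log acceptance ratio.
void tree_mh_step(Tree& tree, const double* X, int nrow, const double* resid,
                  double sigma_mu, double alpha, double beta,
                  const CutpointSet& cuts, const double* move_weights,
                  int min_leaf, int* move, bool* accepted, double* log_alpha,
                  LeafWork& work, LeafWork& scratch, bool work_ready);

double rtnorm_one_sided(double mu, int positive);

#endif
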