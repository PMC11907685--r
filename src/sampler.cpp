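// Gibbs samplers for group testing regression.
//
// Both the BART and the probit-GLM fits share the same latent-variable
// machinery: a sequential sweep over individual true statuses, one-sided
// truncated-normal draws for the probit latents, and stratified conjugate
// beta updates for assay sensitivities/specificities.  They differ only in
// how the linear predictor eta is updated (tree backfitting vs a multivariate
// normal coefficient draw).

#include <RcppArmadillo.h>
#include "tree.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// shared group-testing state
// ---------------------------------------------------------------------------

struct GTData {
  int N, J, L;
  const int* Z;
  const int* pool_start;   // CSR over tests: members of test j are
  const int* pool_idx;     //   pool_idx[pool_start[j] .. pool_start[j+1]-1]
  const int* stratum;      // 0-based stratum per test
  std::vector<int> ind_start, ind_tests;  // CSR over individuals -> tests

  void build_index(int N_) {
    N = N_;
    ind_start.assign(N + 1, 0);
    for (int j = 0; j < J; ++j)
      for (int k = pool_start[j]; k < pool_start[j + 1]; ++k)
        ++ind_start[pool_idx[k] + 1];
    for (int i = 0; i < N; ++i) ind_start[i + 1] += ind_start[i];
    ind_tests.assign(ind_start[N], 0);
    std::vector<int> fill(ind_start.begin(), ind_start.end() - 1);
    for (int j = 0; j < J; ++j)
      for (int k = pool_start[j]; k < pool_start[j + 1]; ++k)
        ind_tests[fill[pool_idx[k]]++] = j;
  }
};

static void recount_pools(const GTData& d, const int* Y, int* pool_pos) {
  for (int j = 0; j < d.J; ++j) {
    int c = 0;
    for (int k = d.pool_start[j]; k < d.pool_start[j + 1]; ++k)
      c += Y[d.pool_idx[k]];
    pool_pos[j] = c;
  }
}

// Per-stratum log accuracy tables, refreshed once per sweep.
struct AccLogs {
  std::vector<double> se1, se0, sp1, sp0;  // log Se, log(1-Se), log(1-Sp), log Sp
  void fill(int L, const double* se, const double* sp) {
    se1.resize(L); se0.resize(L); sp1.resize(L); sp0.resize(L);
    for (int l = 0; l < L; ++l) {
      se1[l] = std::log(se[l]);
      se0[l] = std::log1p(-se[l]);
      sp1[l] = std::log1p(-sp[l]);
      sp0[l] = std::log(sp[l]);
    }
  }
};

// Full conditional P(Y_i = 1 | Y_{-i}, Z, eta, Se, Sp), in log space.
static double status_conditional(const GTData& d, int i, const int* Y,
                                 const int* pool_pos, const double* eta,
                                 const AccLogs& a) {
  double l1 = R::pnorm(eta[i], 0.0, 1.0, 1, 1);   // log Phi
  double l0 = R::pnorm(eta[i], 0.0, 1.0, 0, 1);   // log (1 - Phi)
  for (int k = d.ind_start[i]; k < d.ind_start[i + 1]; ++k) {
    int j = d.ind_tests[k];
    int l = d.stratum[j];
    int sij = pool_pos[j] - Y[i];  // other positives in pool j
    double lse = d.Z[j] ? a.se1[l] : a.se0[l];
    l1 += lse;
    if (sij > 0)
      l0 += lse;
    else
      l0 += d.Z[j] ? a.sp1[l] : a.sp0[l];
  }
  double m = std::max(l0, l1);
  double p1 = std::exp(l1 - m);
  return p1 / (p1 + std::exp(l0 - m));
}

static void sweep_statuses(const GTData& d, int* Y, int* pool_pos,
                           const double* eta, const double* se,
                           const double* sp) {
  AccLogs a;
  a.fill(d.L, se, sp);
  for (int i = 0; i < d.N; ++i) {
    double p1 = status_conditional(d, i, Y, pool_pos, eta, a);
    int y_new = (unif_rand() < p1) ? 1 : 0;
    if (y_new != Y[i]) {
      int delta = y_new - Y[i];
      for (int k = d.ind_start[i]; k < d.ind_start[i + 1]; ++k)
        pool_pos[d.ind_tests[k]] += delta;
      Y[i] = y_new;
    }
  }
}

static void draw_omega(int N, const int* Y, const double* eta, double* omega) {
  for (int i = 0; i < N; ++i)
    omega[i] = rtnorm_one_sided(eta[i], Y[i]);
}

// Conjugate beta updates of (Se, Sp) per stratum; strata flagged known are
// left untouched.
static void update_accuracy(const GTData& d, const int* pool_pos,
                            const int* known, const double* hyper,  // L x 4
                            double* se, double* sp) {
  std::vector<double> se_a(d.L, 0), se_b(d.L, 0), sp_a(d.L, 0), sp_b(d.L, 0);
  for (int j = 0; j < d.J; ++j) {
    int l = d.stratum[j];
    int zt = pool_pos[j] > 0;
    if (zt) { if (d.Z[j]) ++se_a[l]; else ++se_b[l]; }
    else    { if (d.Z[j]) ++sp_b[l]; else ++sp_a[l]; }
  }
  for (int l = 0; l < d.L; ++l) {
    if (known[l]) continue;
    se[l] = R::rbeta(hyper[l] + se_a[l], hyper[d.L + l] + se_b[l]);
    sp[l] = R::rbeta(hyper[2 * d.L + l] + sp_a[l], hyper[3 * d.L + l] + sp_b[l]);
  }
}

// An individual starts positive iff it was tested and every test containing
// it is positive; a negative retest overrides a positive master pool.  (The
// cruder "in any positive test" rule initializes Dorfman data at the master
// pool positivity rate, which seeds the label-switched low-sensitivity mode
// when the accuracies carry diffuse priors.)
static void init_statuses(const GTData& d, int* Y) {
  for (int i = 0; i < d.N; ++i) {
    int n_tests = d.ind_start[i + 1] - d.ind_start[i];
    int all_pos = n_tests > 0;
    for (int k = d.ind_start[i]; k < d.ind_start[i + 1] && all_pos; ++k)
      if (!d.Z[d.ind_tests[k]]) all_pos = 0;
    Y[i] = all_pos;
  }
}

static void init_accuracy(int L, const int* known, const double* hyper,
                          const NumericVector& se0, const NumericVector& sp0,
                          std::vector<double>& se, std::vector<double>& sp) {
  se.resize(L); sp.resize(L);
  for (int l = 0; l < L; ++l) {
    if (known[l]) { se[l] = se0[l]; sp[l] = sp0[l]; }
    else {
      se[l] = hyper[l] / (hyper[l] + hyper[L + l]);
      sp[l] = hyper[2 * L + l] / (hyper[2 * L + l] + hyper[3 * L + l]);
    }
  }
}

// ---------------------------------------------------------------------------
// BART group testing sampler
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_bart_gt(NumericMatrix X, IntegerVector Z, IntegerVector pool_start,
                 IntegerVector pool_idx, IntegerVector stratum, int L,
                 NumericVector se_init, NumericVector sp_init,
                 IntegerVector acc_known, NumericMatrix acc_hyper,
                 List cutpoints, int K, int n_burn, int n_keep, int thin,
                 double alpha, double beta, double sigma_mu,
                 NumericVector move_weights, int min_leaf,
                 NumericMatrix X_test, bool store_eta, bool store_trees) {
  int N = X.nrow(), Q = X.ncol(), J = Z.size(), n_test = X_test.nrow();

  GTData d;
  d.J = J; d.L = L;
  d.Z = INTEGER(Z);
  d.pool_start = INTEGER(pool_start);
  d.pool_idx = INTEGER(pool_idx);
  d.stratum = INTEGER(stratum);
  d.build_index(N);

  CutpointSet cuts = cutpoints_from_list(cutpoints);

  std::vector<int> Y(N), pool_pos(J);
  init_statuses(d, Y.data());
  recount_pools(d, Y.data(), pool_pos.data());

  std::vector<double> se, sp;
  init_accuracy(L, INTEGER(acc_known), REAL(acc_hyper), se_init, sp_init, se, sp);
  // Refresh unknown accuracies once from the data-plausible initial statuses
  // (a first Gibbs update run out of order); starting them at diffuse prior
  // means would make the first status sweep uninformative and can trap the
  // chain in the label-switched low-sensitivity mode.
  update_accuracy(d, pool_pos.data(), INTEGER(acc_known), REAL(acc_hyper),
                  se.data(), sp.data());

  // all trees start as stumps centred at the probit of the initial prevalence
  double ybar = 0.0;
  for (int i = 0; i < N; ++i) ybar += Y[i];
  ybar = std::min(std::max(ybar / N, 1.0 / N), 1.0 - 1.0 / N);
  double mu0 = R::qnorm(ybar, 0.0, 1.0, 1, 0) / K;
  std::vector<Tree> trees(K);
  for (int k = 0; k < K; ++k) trees[k].nodes[0].mu = mu0;

  std::vector<double> eta(N, mu0 * K), omega(N), gk(N), resid(N),
      eta_test(n_test), gk_test(n_test);
  std::vector<int> assign(N);
  LeafWork work, scratch;

  int S = n_keep;
  NumericMatrix se_draws(S, L), sp_draws(S, L);
  IntegerMatrix split_counts(S, Q);
  NumericMatrix eta_draws(store_eta ? S : 0, store_eta ? N : 0);
  NumericMatrix eta_test_draws((store_eta && n_test) ? S : 0,
                               (store_eta && n_test) ? n_test : 0);
  NumericVector prob_train_mean(N), prob_test_mean(n_test), y_mean(N);
  IntegerVector move_attempt(4), move_accept(4);
  List tree_draws(store_trees ? S : 0);

  const double* w = REAL(move_weights);
  int n_iter = n_burn + n_keep * thin;

  for (int it = 0; it < n_iter; ++it) {
    sweep_statuses(d, Y.data(), pool_pos.data(), eta.data(), se.data(), sp.data());
    draw_omega(N, Y.data(), eta.data(), omega.data());

    for (int k = 0; k < K; ++k) {
      Tree& tr = trees[k];
      route_assign(tr, REAL(X), N, assign.data());
      for (int i = 0; i < N; ++i) {
        gk[i] = tr.nodes[assign[i]].mu;
        resid[i] = omega[i] - eta[i] + gk[i];
      }
      stats_from_assign(tr, assign.data(), N, resid.data(), work);
      int move; bool acc; double la;
      tree_mh_step(tr, REAL(X), N, resid.data(), sigma_mu, alpha, beta,
                   cuts, w, min_leaf, &move, &acc, &la, work, scratch, true);
      if (move >= 0) { ++move_attempt[move]; if (acc) ++move_accept[move]; }
      for (int i = 0; i < N; ++i)
        eta[i] += tr.nodes[work.assign[i]].mu - gk[i];
    }

    if ((it & 255) == 255) {  // guard the incremental eta cache against drift
      std::fill(eta.begin(), eta.end(), 0.0);
      for (int k = 0; k < K; ++k) {
        eval_tree(trees[k], REAL(X), N, gk.data());
        for (int i = 0; i < N; ++i) eta[i] += gk[i];
      }
    }

    update_accuracy(d, pool_pos.data(), INTEGER(acc_known), REAL(acc_hyper),
                    se.data(), sp.data());

    int post = it - n_burn;
    if (post >= 0 && (post + 1) % thin == 0) {
      int s = post / thin;
      for (int l = 0; l < L; ++l) { se_draws(s, l) = se[l]; sp_draws(s, l) = sp[l]; }
      for (int k = 0; k < K; ++k)
        for (size_t nd = 0; nd < trees[k].nodes.size(); ++nd)
          if (!trees[k].is_leaf(nd))
            ++split_counts(s, trees[k].nodes[nd].var);
      for (int i = 0; i < N; ++i) {
        prob_train_mean[i] += R::pnorm(eta[i], 0.0, 1.0, 1, 0);
        y_mean[i] += Y[i];
        if (store_eta) eta_draws(s, i) = eta[i];
      }
      if (n_test) {
        std::fill(eta_test.begin(), eta_test.end(), 0.0);
        for (int k = 0; k < K; ++k) {
          eval_tree(trees[k], REAL(X_test), n_test, gk_test.data());
          for (int i = 0; i < n_test; ++i) eta_test[i] += gk_test[i];
        }
        for (int i = 0; i < n_test; ++i) {
          prob_test_mean[i] += R::pnorm(eta_test[i], 0.0, 1.0, 1, 0);
          if (store_eta) eta_test_draws(s, i) = eta_test[i];
        }
      }
      if (store_trees) {
        List ens(K);
        for (int k = 0; k < K; ++k) ens[k] = tree_to_df(trees[k]);
        tree_draws[s] = ens;
      }
    }
  }

  for (int i = 0; i < N; ++i) { prob_train_mean[i] /= S; y_mean[i] /= S; }
  for (int i = 0; i < n_test; ++i) prob_test_mean[i] /= S;

  return List::create(
      _["se_draws"] = se_draws, _["sp_draws"] = sp_draws,
      _["split_counts"] = split_counts, _["eta_draws"] = eta_draws,
      _["eta_test_draws"] = eta_test_draws,
      _["prob_train_mean"] = prob_train_mean,
      _["prob_test_mean"] = prob_test_mean, _["y_mean"] = y_mean,
      _["move_attempt"] = move_attempt, _["move_accept"] = move_accept,
      _["trees"] = tree_draws);
}

// ---------------------------------------------------------------------------
// probit GLM group testing sampler (first-order comparator)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_glm_gt(arma::mat W, IntegerVector Z, IntegerVector pool_start,
                IntegerVector pool_idx, IntegerVector stratum, int L,
                NumericVector se_init, NumericVector sp_init,
                IntegerVector acc_known, NumericMatrix acc_hyper,
                arma::vec prior_mean, arma::mat prior_prec, int n_burn,
                int n_keep, int thin, arma::mat W_test, bool store_eta) {
  int N = W.n_rows, P = W.n_cols, J = Z.size(), n_test = W_test.n_rows;

  GTData d;
  d.J = J; d.L = L;
  d.Z = INTEGER(Z);
  d.pool_start = INTEGER(pool_start);
  d.pool_idx = INTEGER(pool_idx);
  d.stratum = INTEGER(stratum);
  d.build_index(N);

  std::vector<int> Y(N), pool_pos(J);
  init_statuses(d, Y.data());
  recount_pools(d, Y.data(), pool_pos.data());

  std::vector<double> se, sp;
  init_accuracy(L, INTEGER(acc_known), REAL(acc_hyper), se_init, sp_init, se, sp);
  // Refresh unknown accuracies once from the data-plausible initial statuses
  // (a first Gibbs update run out of order); starting them at diffuse prior
  // means would make the first status sweep uninformative and can trap the
  // chain in the label-switched low-sensitivity mode.
  update_accuracy(d, pool_pos.data(), INTEGER(acc_known), REAL(acc_hyper),
                  se.data(), sp.data());

  arma::mat WtW = W.t() * W;
  arma::mat post_prec = WtW + prior_prec;
  arma::mat R_chol = arma::chol(post_prec);  // upper triangular
  arma::vec prior_shift = prior_prec * prior_mean;

  arma::vec beta(P, arma::fill::zeros), omega(N), eta(N, arma::fill::zeros);

  int S = n_keep;
  NumericMatrix beta_draws(S, P), se_draws(S, L), sp_draws(S, L);
  NumericMatrix eta_draws(store_eta ? S : 0, store_eta ? N : 0);
  NumericVector prob_train_mean(N), prob_test_mean(n_test), y_mean(N);

  int n_iter = n_burn + n_keep * thin;
  for (int it = 0; it < n_iter; ++it) {
    sweep_statuses(d, Y.data(), pool_pos.data(), eta.memptr(), se.data(), sp.data());
    for (int i = 0; i < N; ++i) omega[i] = rtnorm_one_sided(eta[i], Y[i]);

    arma::vec z(P);
    for (int p = 0; p < P; ++p) z[p] = norm_rand();
    arma::vec mean = arma::solve(post_prec, W.t() * omega + prior_shift,
                                 arma::solve_opts::likely_sympd);
    beta = mean + arma::solve(arma::trimatu(R_chol), z);
    eta = W * beta;

    update_accuracy(d, pool_pos.data(), INTEGER(acc_known), REAL(acc_hyper),
                    se.data(), sp.data());

    int post = it - n_burn;
    if (post >= 0 && (post + 1) % thin == 0) {
      int s = post / thin;
      for (int p = 0; p < P; ++p) beta_draws(s, p) = beta[p];
      for (int l = 0; l < L; ++l) { se_draws(s, l) = se[l]; sp_draws(s, l) = sp[l]; }
      for (int i = 0; i < N; ++i) {
        prob_train_mean[i] += R::pnorm(eta[i], 0.0, 1.0, 1, 0);
        y_mean[i] += Y[i];
        if (store_eta) eta_draws(s, i) = eta[i];
      }
      if (n_test) {
        arma::vec eta_t = W_test * beta;
        for (int i = 0; i < n_test; ++i)
          prob_test_mean[i] += R::pnorm(eta_t[i], 0.0, 1.0, 1, 0);
      }
    }
  }
  for (int i = 0; i < N; ++i) { prob_train_mean[i] /= S; y_mean[i] /= S; }
  for (int i = 0; i < n_test; ++i) prob_test_mean[i] /= S;

  return List::create(
      _["beta_draws"] = beta_draws, _["se_draws"] = se_draws,
      _["sp_draws"] = sp_draws, _["eta_draws"] = eta_draws,
      _["prob_train_mean"] = prob_train_mean,
      _["prob_test_mean"] = prob_test_mean, _["y_mean"] = y_mean);
}

// ---------------------------------------------------------------------------
// exactness/oracle entry points
// ---------------------------------------------------------------------------

// Gibbs sweeps over the latent statuses only, with eta, Se, Sp held fixed.
// Returns the visited configurations as bitmasks (N <= 30) for comparison
// with exhaustive enumeration of the joint.
// [[Rcpp::export]]
List cpp_status_chain(IntegerVector Z, IntegerVector pool_start,
                      IntegerVector pool_idx, IntegerVector stratum, int L,
                      NumericVector se, NumericVector sp, NumericVector eta,
                      IntegerVector y_init, int n_sweeps) {
  int N = eta.size(), J = Z.size();
  if (N > 30) stop("status chain trace supports N <= 30");
  GTData d;
  d.J = J; d.L = L;
  d.Z = INTEGER(Z);
  d.pool_start = INTEGER(pool_start);
  d.pool_idx = INTEGER(pool_idx);
  d.stratum = INTEGER(stratum);
  d.build_index(N);

  std::vector<int> Y(y_init.begin(), y_init.end()), pool_pos(J);
  recount_pools(d, Y.data(), pool_pos.data());

  IntegerVector trace(n_sweeps);
  NumericVector y_mean(N);
  for (int s = 0; s < n_sweeps; ++s) {
    sweep_statuses(d, Y.data(), pool_pos.data(), REAL(eta), REAL(se), REAL(sp));
    int mask = 0;
    for (int i = 0; i < N; ++i) {
      mask |= Y[i] << i;
      y_mean[i] += Y[i];
    }
    trace[s] = mask;
  }
  for (int i = 0; i < N; ++i) y_mean[i] /= n_sweeps;
  return List::create(_["trace"] = trace, _["y_mean"] = y_mean);
}

// Full-conditional probabilities P(Y_i=1 | Y_{-i}, Z) for every i at the
// supplied configuration (no sampling).
// [[Rcpp::export]]
NumericVector cpp_status_conditional(IntegerVector Z, IntegerVector pool_start,
                                     IntegerVector pool_idx,
                                     IntegerVector stratum, int L,
                                     NumericVector se, NumericVector sp,
                                     NumericVector eta, IntegerVector y) {
  int N = eta.size(), J = Z.size();
  GTData d;
  d.J = J; d.L = L;
  d.Z = INTEGER(Z);
  d.pool_start = INTEGER(pool_start);
  d.pool_idx = INTEGER(pool_idx);
  d.stratum = INTEGER(stratum);
  d.build_index(N);
  std::vector<int> Y(y.begin(), y.end()), pool_pos(J);
  recount_pools(d, Y.data(), pool_pos.data());
  NumericVector out(N);
  AccLogs a;
  a.fill(L, REAL(se), REAL(sp));
  for (int i = 0; i < N; ++i)
    out[i] = status_conditional(d, i, Y.data(), pool_pos.data(), REAL(eta), a);
  return out;
}

// ---------------------------------------------------------------------------
// tree-level entry points (unit testing / serialization)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_tree_eval(DataFrame tree, NumericMatrix X) {
  Tree t = tree_from_df(tree);
  NumericVector out(X.nrow());
  eval_tree(t, REAL(X), X.nrow(), REAL(out));
  return out;
}

// [[Rcpp::export]]
double cpp_tree_log_prior(DataFrame tree, List cutpoints, double alpha,
                          double beta) {
  Tree t = tree_from_df(tree);
  CutpointSet cuts = cutpoints_from_list(cutpoints);
  return tree_log_prior(t, alpha, beta, cuts);
}

// [[Rcpp::export]]
double cpp_tree_intloglik(DataFrame tree, NumericMatrix X, NumericVector resid,
                          double sigma_mu) {
  Tree t = tree_from_df(tree);
  return tree_integrated_loglik(t, REAL(X), X.nrow(), REAL(resid), sigma_mu);
}

// [[Rcpp::export]]
List cpp_tree_mh(DataFrame tree, List cutpoints, NumericMatrix X,
                 NumericVector resid, double sigma_mu, double alpha,
                 double beta, NumericVector move_weights, int min_leaf) {
  Tree t = tree_from_df(tree);
  CutpointSet cuts = cutpoints_from_list(cutpoints);
  int move; bool acc; double la;
  LeafWork work, scratch;
  tree_mh_step(t, REAL(X), X.nrow(), REAL(resid), sigma_mu, alpha, beta, cuts,
               REAL(move_weights), min_leaf, &move, &acc, &la, work, scratch,
               false);
  CharacterVector names = CharacterVector::create("grow", "prune", "change",
                                                  "swap");
  return List::create(_["tree"] = tree_to_df(t),
                      _["move"] = (move >= 0)
                          ? as<std::string>(names[move]) : "none",
                      _["accepted"] = acc, _["log_alpha"] = la);
}

// [[Rcpp::export]]
NumericVector cpp_rtnorm(NumericVector mu, LogicalVector positive) {
  int n = mu.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = rtnorm_one_sided(mu[i], positive[i]);
  return out;
}
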