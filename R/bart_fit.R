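#' Fit the BART group testing model
#'
#' Posterior sampling for the probit sum-of-trees model from group testing
#' data via the two-stage data-augmentation Gibbs sampler.  Each sweep
#' updates, in order: every latent individual status from its full
#' conditional (sequentially, with per-pool positive counts maintained
#' incrementally), the truncated-normal probit latents, every tree by one
#' Metropolis-Hastings backfitting step plus conjugate leaf redraws, and the
#' assay accuracies of every stratum not flagged known by stratified
#' conjugate beta draws.
#'
#' @param data a [group_testing_data()] object (must pass
#'   [validate_group_data()]).
#' @param accuracy a [assay_accuracy()] object with at least as many strata
#'   as appear in `data$stratum`.  Known strata are held fixed at their
#'   `se`/`sp`; unknown strata are initialized at their beta prior means and
#'   sampled.
#' @param K number of trees (20 or 200 are the customary configurations).
#' @param n_burn,n_keep burn-in and retained sweeps.
#' @param thin thinning interval (default 1: every post-burn-in sweep kept).
#' @param prior a [tree_prior()]; defaults to `tree_prior(K)`.
#' @param move_weights GROW/PRUNE/CHANGE/SWAP selection weights.
#' @param X_test optional covariate matrix at which `eta` is evaluated for
#'   every retained draw (out-of-sample prediction).
#' @param store_eta keep the full `S x N` (and `S x n_test`) matrices of
#'   linear-predictor draws; disable for long replicate studies to save
#'   memory (posterior mean probabilities are always accumulated).
#' @param store_trees keep the serialized tree ensembles of every retained
#'   draw (needed by [predict.gtbart_fit()]).
#' @param seed optional integer; if supplied, `set.seed(seed)` is called so
#'   the run is exactly reproducible.
#'
#' @return An object of class `gtbart_fit`: a list with `se_draws`,
#'   `sp_draws` (S x L), `eta_draws`, `eta_test_draws` (if stored),
#'   `prob_train_mean`, `prob_test_mean`, `y_mean` (posterior probability of
#'   each latent status), `split_counts` (S x Q decision-rule counts per
#'   covariate), `trees` (if stored), move acceptance diagnostics, and the
#'   fit configuration.
#' @seealso [gt_glm()] for the first-order probit GLM comparator fitted with
#'   the identical augmentation.
#' @export
#' @examples
#' sim <- gt_simulate("M3", N = 200, protocol = "DT", seed = 1)
#' fit <- gt_bart(sim$data, assay_accuracy(c(0.95, 0.98), c(0.98, 0.99)),
#'                K = 10, n_burn = 50, n_keep = 50, seed = 2)
#' accuracy_summary(fit)
gt_bart <- function(data, accuracy, K = 200, n_burn = 2500, n_keep = 2500,
                    thin = 1, prior = tree_prior(K),
                    move_weights = c(0.25, 0.25, 0.40, 0.10),
                    X_test = NULL, store_eta = TRUE, store_trees = FALSE,
                    seed = NULL) {
  viol <- validate_group_data(data)
  if (length(viol)) stop("invalid group testing data: ", viol[1])
  if (accuracy$L < data$L)
    stop(sprintf("data use %d strata but accuracy has %d", data$L, accuracy$L))
  stopifnot(n_burn >= 1, n_keep >= 1, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(X_test)) X_test <- matrix(0, 0, ncol(data$X))

  csr <- pool_csr(data)
  res <- cpp_bart_gt(
    data$X, data$Z, csr$start, csr$idx, data$stratum - 1L, accuracy$L,
    accuracy$se, accuracy$sp, as.integer(accuracy$known), accuracy$hyper,
    make_cutpoints(data$X), as.integer(K), as.integer(n_burn),
    as.integer(n_keep), as.integer(thin), prior$alpha, prior$beta,
    prior$sigma_mu, move_weights, 1L, as.matrix(X_test), store_eta,
    store_trees)

  colnames(res$split_counts) <- colnames(data$X)
  structure(c(res, list(
    model = "bart", L = accuracy$L, Q = ncol(data$X), K = as.integer(K),
    n_burn = n_burn, n_keep = n_keep, thin = thin, prior = prior,
    accuracy_prior = accuracy, seed = seed
  )), class = "gtbart_fit")
}

#' Full-conditional probability of each latent status
#'
#' For every individual `i`, computes
#' `P(Y_i = 1 | Y_{-i}, Z, eta, Se, Sp)` — the Bernoulli probability used by
#' the Gibbs status sweep — at the supplied status configuration.  The
#' positive branch multiplies `Phi(eta_i)` by the sensitivity factor of
#' every test containing `i`; the negative branch uses the sensitivity
#' factor only for tests whose pool holds another positive (`s_ij > 0`) and
#' the specificity factor otherwise.  Computed in log space with
#' max-subtraction, so long retest histories are safe.
#'
#' @param data a [group_testing_data()] object.
#' @param accuracy a [assay_accuracy()] object (its current `se`/`sp` are
#'   used).
#' @param eta linear predictor `eta(x_i)`, length `N`.
#' @param y current status configuration, length `N`.
#' @return Numeric vector of `N` probabilities in `[0, 1]`.
#' @export
status_probability <- function(data, accuracy, eta, y) {
  stopifnot(length(eta) == data$N, length(y) == data$N)
  csr <- pool_csr(data)
  cpp_status_conditional(data$Z, csr$start, csr$idx, data$stratum - 1L,
                         accuracy$L, accuracy$se, accuracy$sp, eta,
                         as.integer(y))
}

#' @export
print.gtbart_fit <- function(x, ...) {
  cat(sprintf("BART group testing fit: K=%d trees, %d retained draws\n",
              x$K, x$n_keep))
  att <- pmax(x$move_attempt, 1L)
  cat(sprintf("  move acceptance (grow/prune/change/swap): %s\n",
              paste(sprintf("%.2f", x$move_accept / att), collapse = "/")))
  print(accuracy_summary(x))
  invisible(x)
}
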