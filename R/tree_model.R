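#' Tree ensemble prior settings
#'
#' Hyperparameters of the regularization prior on each regression tree and
#' its terminal-node values.  A node at depth `d` is interior with
#' probability `alpha * (1 + d)^(-beta)`; split variables are uniform over
#' the covariates and cutoffs uniform over the observed values of the chosen
#' covariate; leaf values are `N(0, sigma_mu^2)`.
#'
#' The default leaf scale is the canonical probit-BART choice
#' `sigma_mu = 3 / (H * sqrt(K))` with `H = 2`, which keeps the prior on
#' `eta(x)` spread over roughly (-3, 3) regardless of `K`;
#' `sigma_mu_form = "printed"` selects `3 / (H * K)` instead, which shrinks
#' the total signal towards zero as `K` grows.
#'
#' @param K number of trees.
#' @param alpha,beta depth-penalty parameters, defaults 0.95 and 2.
#' @param H leaf-scale divisor, default 2.
#' @param sigma_mu_form `"sqrt"` (default) or `"printed"`; see above.
#' @param sigma_mu optional explicit override of the leaf standard deviation.
#' @return A list of class `gt_tree_prior` with fields `alpha`, `beta`, `K`,
#'   `H`, `sigma_mu`.
#' @export
tree_prior <- function(K, alpha = 0.95, beta = 2, H = 2,
                       sigma_mu_form = c("sqrt", "printed"),
                       sigma_mu = NULL) {
  sigma_mu_form <- match.arg(sigma_mu_form)
  stopifnot(alpha > 0, alpha < 1, beta >= 0, K >= 1, H > 0)
  if (is.null(sigma_mu))
    sigma_mu <- if (sigma_mu_form == "sqrt") 3 / (H * sqrt(K)) else 3 / (H * K)
  structure(list(alpha = alpha, beta = beta, K = as.integer(K), H = H,
                 sigma_mu = sigma_mu),
            class = "gt_tree_prior")
}

#' Cutpoint sets from observed covariates
#'
#' The candidate split locations for each covariate are its unique observed
#' values, precomputed once per fit.
#'
#' @param X covariate matrix.
#' @return List of sorted numeric vectors, one per column of `X`.
#' @export
make_cutpoints <- function(X) {
  X <- as.matrix(X)
  lapply(seq_len(ncol(X)), function(q) sort(unique(X[, q])))
}

#' Single-leaf tree
#'
#' @param mu the leaf value.
#' @return A tree node table (see [tree_evaluate()] for the layout).
#' @export
tree_stump <- function(mu = 0) {
  data.frame(node = 1L, parent = 0L, left = 0L, right = 0L, var = 0L,
             cutoff = NA_real_, mu = mu)
}

#' Evaluate a regression tree
#'
#' Trees are represented as data frames with one row per node and columns
#' `node`, `parent`, `left`, `right` (1-based ids, 0 = none), `var`
#' (splitting covariate, 0 for a leaf), `cutoff`, and `mu` (leaf value, `NA`
#' for interior nodes).  An observation is routed from the root, going left
#' iff `x[var] <= cutoff`, and receives the value of the terminal node it
#' reaches.
#'
#' @param tree a tree node table.
#' @param X covariate matrix (rows are observations).
#' @return Numeric vector of fitted values `g(x; T, M)`.
#' @export
tree_evaluate <- function(tree, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  cpp_tree_eval(tree, as.matrix(X))
}

#' Evaluate a sum-of-trees ensemble
#'
#' @param trees list of tree node tables.
#' @param X covariate matrix.
#' @return `eta(x) = sum_k g(x; T_k, M_k)` for every row of `X`.
#' @export
ensemble_evaluate <- function(trees, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  Reduce(`+`, lapply(trees, function(tr) tree_evaluate(tr, X)),
         numeric(nrow(X)))
}

#' Log prior probability of a tree structure
#'
#' An interior node at depth `d` contributes
#' `log(alpha (1+d)^-beta) + log(1/Q') + log(1/ncut(q))` (uniform rule
#' choice, `Q'` the number of covariates with at least one cutpoint); a
#' terminal node contributes `log(1 - alpha (1+d)^-beta)`.
#'
#' @param tree a tree node table.
#' @param cutpoints list of per-covariate cutpoint vectors
#'   ([make_cutpoints()]).
#' @param alpha,beta depth-penalty parameters.
#' @return Log prior probability (rules included, leaf values excluded).
#' @export
tree_log_prior <- function(tree, cutpoints, alpha = 0.95, beta = 2) {
  cpp_tree_log_prior(tree, cutpoints, alpha, beta)
}

#' Conjugate posterior for one leaf value
#'
#' With unit-variance normal residuals `r_1..r_n` routed to a leaf and prior
#' `mu ~ N(0, sigma_mu^2)`, the full conditional of the leaf value is normal
#' with variance `1 / (n + sigma_mu^-2)` and mean `sum(r)` times that
#' variance.  An empty leaf reverts to the prior.
#'
#' @param resid residuals routed to the leaf (possibly length 0).
#' @param sigma_mu leaf prior standard deviation.
#' @return `c(mean, variance)` of the full conditional.
#' @export
leaf_posterior <- function(resid, sigma_mu) {
  v <- 1 / (length(resid) + sigma_mu^-2)
  c(mean = sum(resid) * v, variance = v)
}

#' Integrated (marginal) log-likelihood of a tree structure
#'
#' Unit-variance residual likelihood with the leaf values integrated out
#' under their `N(0, sigma_mu^2)` prior; the quantity compared in the
#' backfitting Metropolis-Hastings step.  Each non-empty leaf `t` with `n_t`
#' residuals contributes
#' `-(n_t/2) log(2 pi) - log(1 + n_t sigma_mu^2)/2 - sum(r^2)/2 +
#'  sigma_mu^2 sum(r)^2 / (2 (1 + n_t sigma_mu^2))`.
#'
#' @param tree a tree node table.
#' @param X covariate matrix (defines routing).
#' @param resid partial residuals, one per row of `X`.
#' @param sigma_mu leaf prior standard deviation.
#' @return The marginal log-likelihood.
#' @export
tree_integrated_loglik <- function(tree, X, resid, sigma_mu) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  cpp_tree_intloglik(tree, as.matrix(X), resid, sigma_mu)
}

#' One Metropolis-Hastings step on a tree
#'
#' Proposes one structural move — GROW (split a random leaf with a random
#' rule), PRUNE (collapse a random parent of two leaves), CHANGE (redraw a
#' random interior rule) or SWAP (swap rules of a parent-child interior
#' pair) — accepts or rejects it using the integrated likelihood, the tree
#' prior and the proposal ratio, and then redraws all leaf values from their
#' conjugate full conditionals.  Proposals that would route fewer than
#' `min_leaf` training observations to any leaf are rejected outright.
#'
#' @inheritParams tree_integrated_loglik
#' @param cutpoints list of per-covariate candidate cutoffs.
#' @param alpha,beta tree prior parameters.
#' @param move_weights selection weights for GROW/PRUNE/CHANGE/SWAP,
#'   renormalized over the moves available in the current state.
#' @param min_leaf minimum training observations per leaf (0 disables the
#'   check, e.g. for prior-only chains).
#' @return List with the updated `tree`, the attempted `move`, `accepted`,
#'   and `log_alpha` (the log acceptance ratio before truncation at 0).
#' @export
tree_mh_step <- function(tree, cutpoints, X, resid, sigma_mu,
                         alpha = 0.95, beta = 2,
                         move_weights = c(0.25, 0.25, 0.40, 0.10),
                         min_leaf = 1) {
  if (is.null(dim(X))) X <- matrix(X, nrow = length(X))
  cpp_tree_mh(tree, cutpoints, as.matrix(X), resid, sigma_mu, alpha, beta,
              move_weights, as.integer(min_leaf))
}

#' Serialize trees to JSON
#'
#' Writes a list of tree node tables (one posterior draw of the ensemble) to
#' a documented JSON form: an array of trees, each an array of node records
#' `{node, parent, left, right, var, cutoff, mu}`.
#'
#' @param trees list of tree node tables.
#' @param path output file.
#' @export
write_trees_json <- function(trees, path) {
  jsonlite::write_json(lapply(trees, as.data.frame), path, digits = NA,
                       na = "null", dataframe = "rows")
}

#' @rdname write_trees_json
#' @return `read_trees_json()` returns the list of tree node tables.
#' @export
read_trees_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- list(raw)
  lapply(raw, function(df) {
    df <- as.data.frame(df)
    for (col in c("cutoff", "mu")) {
      if (is.null(df[[col]])) df[[col]] <- NA_real_
      df[[col]] <- as.numeric(df[[col]])
    }
    for (col in c("node", "parent", "left", "right", "var"))
      df[[col]] <- as.integer(df[[col]])
    df[c("node", "parent", "left", "right", "var", "cutoff", "mu")]
  })
}
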