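#' Conjugate posterior of the probit GLM coefficients
#'
#' Given current probit latents `omega` with unit residual variance and a
#' `N(mu0, Sigma0)` prior, the coefficient full conditional is
#' `N(V (W'omega + Sigma0^-1 mu0), V)` with `V = (W'W + Sigma0^-1)^-1`.
#'
#' @param W design matrix (may have zero rows: the prior is returned).
#' @param omega probit latents, one per row of `W`.
#' @param prior_mean,prior_cov prior mean vector and covariance matrix.
#' @return List with `mean` and `cov` of the full conditional.
#' @export
glm_beta_posterior <- function(W, omega, prior_mean, prior_cov) {
  W <- as.matrix(W)
  prec0 <- solve(prior_cov)
  V <- solve(crossprod(W) + prec0)
  m <- V %*% (crossprod(W, omega) + prec0 %*% prior_mean)
  list(mean = drop(m), cov = V)
}

#' Fit the first-order probit GLM comparator
#'
#' The Bayesian probit GLM for group testing: identical latent-status,
#' probit-latent and accuracy updates as [gt_bart()], with the sum of trees
#' replaced by the linear predictor `eta_i = w_i' beta` and a multivariate
#' normal conjugate draw for `beta`.  Covariates enter linearly;
#' the default prior is the diffuse `beta ~ N(0, 100 I)`.
#'
#' @inheritParams gt_bart
#' @param intercept prepend an intercept column (default `TRUE`).
#' @param prior_mean,prior_cov normal prior on the coefficients; scalars are
#'   expanded (`prior_cov = 100` means `100 * I`).
#' @return An object of class `gtglm_fit` with `beta_draws` (S x P) in place
#'   of the tree components; other fields as in [gt_bart()].
#' @export
#' @examples
#' sim <- gt_simulate("M2", N = 300, protocol = "DT", seed = 1,
#'                    accuracy_truth = assay_accuracy(c(0.95, 0.95),
#'                                                    c(0.98, 0.98),
#'                                                    known = TRUE))
#' fit <- gt_glm(sim$data, sim$design$accuracy_truth,
#'               n_burn = 100, n_keep = 100, seed = 2)
#' colMeans(fit$beta_draws)
gt_glm <- function(data, accuracy, intercept = TRUE, prior_mean = 0,
                   prior_cov = 100, n_burn = 2500, n_keep = 2500, thin = 1,
                   X_test = NULL, store_eta = TRUE, seed = NULL) {
  viol <- validate_group_data(data)
  if (length(viol)) stop("invalid group testing data: ", viol[1])
  if (accuracy$L < data$L)
    stop(sprintf("data use %d strata but accuracy has %d", data$L, accuracy$L))
  stopifnot(n_burn >= 1, n_keep >= 1, thin >= 1)
  if (!is.null(seed)) set.seed(seed)

  W <- if (intercept) cbind(`(Intercept)` = 1, data$X) else data$X
  P <- ncol(W)
  if (length(prior_mean) == 1) prior_mean <- rep(prior_mean, P)
  if (length(prior_cov) == 1) prior_cov <- diag(prior_cov, P)
  prior_prec <- solve(prior_cov)
  if (qr(W)$rank < P) stop("design matrix is rank deficient")

  W_test <- if (is.null(X_test)) matrix(0, 0, P) else {
    if (intercept) cbind(1, as.matrix(X_test)) else as.matrix(X_test)
  }

  csr <- pool_csr(data)
  res <- cpp_glm_gt(
    W, data$Z, csr$start, csr$idx, data$stratum - 1L, accuracy$L,
    accuracy$se, accuracy$sp, as.integer(accuracy$known), accuracy$hyper,
    prior_mean, prior_prec, as.integer(n_burn), as.integer(n_keep),
    as.integer(thin), W_test, store_eta)

  colnames(res$beta_draws) <- colnames(W)
  structure(c(res, list(
    model = "glm", L = accuracy$L, P = P, intercept = intercept,
    n_burn = n_burn, n_keep = n_keep, thin = thin,
    prior_mean = prior_mean, prior_cov = prior_cov,
    accuracy_prior = accuracy, seed = seed
  )), class = "gtglm_fit")
}

#' @export
print.gtglm_fit <- function(x, ...) {
  cat(sprintf("Probit GLM group testing fit: %d coefficients, %d draws\n",
              x$P, x$n_keep))
  est <- colMeans(x$beta_draws)
  qs <- apply(x$beta_draws, 2, quantile, c(0.025, 0.975))
  print(data.frame(mean = est, lower = qs[1, ], upper = qs[2, ]))
  print(accuracy_summary(x))
  invisible(x)
}
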