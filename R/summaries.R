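#' Variable inclusion proportions
#'
#' The relative importance measure for BART: for retained draw `s`, let
#' `z_qs` be the number of decision rules splitting on covariate `q` and
#' `z_.s` the total number of rules in the ensemble; the inclusion
#' proportion is `v_q = mean_s(z_qs / z_.s)`.  Draws in which the ensemble
#' is all stumps (`z_.s = 0`) contribute the uninformative `1/Q` to every
#' covariate so that `v` remains a proper distribution.  Proportions are
#' most interpretable with a small number of trees (e.g. `K = 20`), where
#' covariates must compete for splits.
#'
#' @param x a `gtbart_fit`, or an `S x Q` matrix of per-draw split counts.
#' @return Numeric vector `v` of length Q summing to 1.
#' @export
variable_inclusion <- function(x) {
  counts <- if (inherits(x, "gtbart_fit")) x$split_counts else as.matrix(x)
  Q <- ncol(counts)
  tot <- rowSums(counts)
  shares <- counts / tot                  # rows with tot = 0 become NaN
  shares[tot == 0, ] <- 1 / Q
  v <- colMeans(shares)
  names(v) <- colnames(counts)
  v
}

#' Posterior disease-probability predictions
#'
#' Per-observation posterior mean and equal-tail quantiles of
#' `Phi(eta(x))` across the retained draws.
#'
#' @param fit a `gtbart_fit` or `gtglm_fit` with `store_eta = TRUE`.
#' @param which `"train"` for the fitted individuals, `"test"` for the
#'   `X_test` grid supplied at fit time.
#' @param level credible level for the equal-tail interval (default 0.95).
#' @return Data frame with columns `mean`, `lower`, `upper`.
#' @export
predict_prob <- function(fit, which = c("train", "test"), level = 0.95) {
  which <- match.arg(which)
  eta <- if (which == "train") fit$eta_draws else fit$eta_test_draws
  if (is.null(eta) || nrow(eta) == 0)
    stop("fit was run without store_eta = TRUE (or no X_test was supplied)")
  p <- pnorm(eta)
  a <- (1 - level) / 2
  qs <- apply(p, 2, quantile, probs = c(a, 1 - a))
  data.frame(mean = colMeans(p), lower = qs[1, ], upper = qs[2, ])
}

#' Predict from stored tree ensembles
#'
#' Evaluates every retained ensemble draw on new covariates; requires the
#' fit to have been run with `store_trees = TRUE`.
#'
#' @param object a `gtbart_fit`.
#' @param newdata covariate matrix.
#' @param ... unused.
#' @return Matrix of `eta` draws, `S x nrow(newdata)`.
#' @export
predict.gtbart_fit <- function(object, newdata, ...) {
  if (length(object$trees) == 0)
    stop("refit with store_trees = TRUE to predict on new data")
  newdata <- as.matrix(newdata)
  t(vapply(object$trees, function(ens) ensemble_evaluate(ens, newdata),
           numeric(nrow(newdata))))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counting one half.
#'
#' @param scores numeric risk scores.
#' @param truth binary true statuses (must contain both classes).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both positive and negative statuses")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical interval coverage
#'
#' Fraction of true values falling inside their closed intervals.
#'
#' @param lower,upper interval endpoints (`lower <= upper`).
#' @param truth true values, same length.
#' @return Coverage proportion in `[0, 1]`.
#' @export
coverage_rate <- function(lower, upper, truth) {
  if (length(lower) != length(truth) || length(upper) != length(truth))
    stop("interval and truth lengths differ")
  if (any(lower > upper)) stop("lower > upper")
  mean(lower <= truth & truth <= upper)
}

#' Posterior summary of assay accuracies
#'
#' @param fit a `gtbart_fit` or `gtglm_fit`.
#' @param level credible level (default 0.95, equal-tail).
#' @return Data frame with one row per stratum and parameter (Se, Sp):
#'   posterior mean, interval endpoints, and whether the stratum was known.
#' @export
accuracy_summary <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  one <- function(draws, what) {
    data.frame(
      stratum = seq_len(ncol(draws)), parameter = what,
      mean = colMeans(draws),
      lower = apply(draws, 2, quantile, a),
      upper = apply(draws, 2, quantile, 1 - a),
      known = fit$accuracy_prior$known[seq_len(ncol(draws))])
  }
  out <- rbind(one(fit$se_draws, "Se"), one(fit$sp_draws, "Sp"))
  rownames(out) <- NULL
  out[order(out$stratum, out$parameter), ]
}

#' Replicate simulation study
#'
#' Runs the full simulate-fit-evaluate loop: for each replicate and
#' population model, simulate a population, apply each protocol, fit each
#' requested method, and record classification and accuracy-recovery
#' metrics.  Replicate `r` uses master seed `seed + r`, so the table is
#' reproducible bit-exactly and independent reruns of a replicate agree.
#'
#' @param config a list (or JSON file parsed to one) with entries:
#'   `models` (subset of "M1","M2","M3"), `protocols` (subset of
#'   "IT","MPT","DT"), `methods` (subset of "bart","glm"), `n_reps`, `N`,
#'   `pool_size`, `n_test` (fresh out-of-sample individuals per replicate),
#'   `K`, `n_burn`, `n_keep`, `se`, `sp` (generating accuracies per
#'   stratum), `known` (logical), `prior` (beta hyperparameters), `seed`.
#'   Missing entries take the defaults of the scaled-down study
#'   (`N = 1000`, `K = 20`, 1000/1000 sweeps, pools of 4).
#' @return A tidy data frame with columns `replicate`, `model`, `protocol`,
#'   `method`, `metric`, `value`.  Metrics include `auc_in`, `auc_out`,
#'   per-stratum `se*_mean`, `sp*_mean` and interval endpoints (when
#'   estimated), inclusion proportions `v1..vQ` (BART) and coefficient
#'   posterior means `beta0..` (GLM).
#' @export
run_simulation_study <- function(config = list()) {
  cf <- utils::modifyList(list(
    models = "M3", protocols = "DT", methods = c("bart", "glm"),
    n_reps = 10, N = 1000, pool_size = 4, n_test = 1000, K = 20,
    n_burn = 1000, n_keep = 1000, se = c(0.95, 0.98), sp = c(0.98, 0.99),
    known = FALSE, prior = c(1, 1, 1, 1), seed = 1), config)
  acc <- assay_accuracy(cf$se, cf$sp, cf$known, cf$prior)
  rows <- list()
  emit <- function(rep, model, protocol, method, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      replicate = rep, model = model, protocol = protocol, method = method,
      metric = metric, value = as.numeric(value))
  }

  for (r in seq_len(cf$n_reps)) {
    for (model in cf$models) {
      master <- cf$seed + r
      design0 <- sim_design(model, cf$N, cf$pool_size, "DT", acc,
                            seed = master)
      truth <- simulate_statuses(design0)
      set.seed(master + 777000L)
      test_truth <- local({
        d <- sim_design(model, cf$n_test, cf$pool_size, "DT", acc,
                        seed = master + 777000L)
        simulate_statuses(d)
      })
      for (protocol in cf$protocols) {
        design <- sim_design(model, cf$N, cf$pool_size, protocol, acc,
                             seed = master)
        data <- run_protocol(truth, design)
        for (method in cf$methods) {
          set.seed(master + 31L * match(method, c("bart", "glm")))
          fit <- if (method == "bart") {
            gt_bart(data, acc, K = cf$K, n_burn = cf$n_burn,
                    n_keep = cf$n_keep, X_test = test_truth$X,
                    store_eta = FALSE)
          } else {
            gt_glm(data, acc, n_burn = cf$n_burn, n_keep = cf$n_keep,
                   X_test = test_truth$X, store_eta = FALSE)
          }
          emit(r, model, protocol, method, "auc_in",
               auc_rank(fit$prob_train_mean, truth$y_true))
          emit(r, model, protocol, method, "auc_out",
               auc_rank(fit$prob_test_mean, test_truth$y_true))
          if (any(!acc$known)) {
            summ <- accuracy_summary(fit)
            for (i in seq_len(nrow(summ))) {
              if (summ$known[i]) next
              stem <- sprintf("%s%d", tolower(summ$parameter[i]),
                              summ$stratum[i])
              emit(r, model, protocol, method, paste0(stem, "_mean"),
                   summ$mean[i])
              emit(r, model, protocol, method, paste0(stem, "_lower"),
                   summ$lower[i])
              emit(r, model, protocol, method, paste0(stem, "_upper"),
                   summ$upper[i])
            }
          }
          if (method == "bart") {
            v <- variable_inclusion(fit)
            for (q in seq_along(v))
              emit(r, model, protocol, method, paste0("v", q), v[q])
          } else {
            b <- colMeans(fit$beta_draws)
            for (p in seq_along(b))
              emit(r, model, protocol, method, paste0("beta", p - 1L), b[p])
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
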