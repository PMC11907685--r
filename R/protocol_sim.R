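#' Regression surfaces used in the simulation designs
#'
#' Evaluates the latent probit-scale surface f(x) for the three built-in
#' designs with Q = 3 covariates (x1, x2 uniform on (0,10), x3 binary):
#' \describe{
#'   \item{M1}{`sin(pi * x1) - 1.25` — highly non-linear, only x1 active.}
#'   \item{M2}{`-0.85 + 0.55 x1 - 1.25 x2 - 0.35 x3` — linear, the case where
#'     a first-order probit GLM is correctly specified.}
#'   \item{M3}{`-sin(x1 / 3) - x1 * x3 + x3` — smooth non-linearity plus an
#'     interaction with the binary covariate; x2 inactive.}
#' }
#' Disease probabilities are `pnorm(true_f(model, X))`.
#'
#' @param model `"M1"`, `"M2"`, `"M3"`, or `"custom"` (then `f` is used).
#' @param X covariate matrix with Q = 3 columns (or a single row as vector).
#' @param f for `model = "custom"`, a function taking the covariate matrix
#'   and returning the vector f(x).
#' @return Numeric vector of f(x), one entry per row of `X`.
#' @export
#' @examples
#' true_f("M1", c(0.5, 0, 0))       # sin(pi/2) - 1.25 = -0.25
#' true_f("M2", c(0, 0, 0))         # intercept only: -0.85
true_f <- function(model, X, f = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  switch(as.character(model),
    M1 = sin(pi * X[, 1]) - 1.25,
    M2 = {
      beta <- c(-0.85, 0.55, -1.25, -0.35)
      drop(beta[1] + X[, 1:3, drop = FALSE] %*% beta[2:4])
    },
    M3 = -sin(X[, 1] / 3) - X[, 1] * X[, 3] + X[, 3],
    custom = {
      if (!is.function(f)) stop("model 'custom' requires a function f")
      drop(f(X))
    },
    stop(sprintf("unknown model '%s'", model))
  )
}

#' Simulation design
#'
#' Bundles everything needed to generate one synthetic group testing data
#' set: the true regression surface, population size, pooling protocol,
#' master pool size, the generating assay accuracies, and a seed.  Under
#' Dorfman testing stratum 1 holds the master pool tests and stratum 2 the
#' individual retests, so `accuracy_truth` must have at least 2 strata for
#' `protocol = "DT"`.
#'
#' @param model `"M1"`, `"M2"`, `"M3"` or `"custom"`; see [true_f()].
#' @param N number of individuals (`N >= pool_size`).
#' @param pool_size master pool size (default 4).
#' @param protocol `"IT"` (individual), `"MPT"` (master pools only) or
#'   `"DT"` (Dorfman two-stage).
#' @param accuracy_truth a [assay_accuracy()] object holding the generating
#'   sensitivities/specificities per stratum.
#' @param seed integer master seed; covariates/statuses and protocol noise
#'   use streams derived from it, so different protocols can be compared on
#'   the identical underlying population.
#' @param f custom surface for `model = "custom"`.
#' @return An object of class `gt_design`.
#' @export
sim_design <- function(model = "M1", N = 5000, pool_size = 4,
                       protocol = c("DT", "MPT", "IT"),
                       accuracy_truth = assay_accuracy(c(0.95, 0.98),
                                                       c(0.98, 0.99)),
                       seed = NULL, f = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(pool_size >= 1, N >= pool_size)
  if (protocol == "DT" && accuracy_truth$L < 2)
    stop("Dorfman testing needs accuracies for strata 1 (pools) and 2 (retests)")
  structure(list(model = model, N = as.integer(N),
                 pool_size = as.integer(pool_size), protocol = protocol,
                 accuracy_truth = accuracy_truth, seed = seed, f = f),
            class = "gt_design")
}

#' Simulate covariates and true disease statuses
#'
#' Draws x1, x2 ~ uniform(0, 10) and x3 ~ Bernoulli(0.5) for N individuals,
#' then true statuses Y_i ~ Bernoulli(Phi(f(x_i))) independently.
#'
#' @param design a [sim_design()] object.
#' @return A list of class `gt_truth` with `X` (N x 3), `p_true`
#'   (`pnorm(f(X))`) and `y_true` (0/1).
#' @export
simulate_statuses <- function(design) {
  if (!is.null(design$seed)) set.seed(design$seed)
  N <- design$N
  X <- cbind(x1 = runif(N, 0, 10), x2 = runif(N, 0, 10),
             x3 = rbinom(N, 1, 0.5))
  p <- pnorm(true_f(design$model, X, design$f))
  structure(list(X = X, p_true = p, y_true = rbinom(N, 1, p)),
            class = "gt_truth")
}

#' Randomly partition individuals into master pools
#'
#' Individuals are assigned to pools of size `pool_size` by a random
#' permutation; when `pool_size` does not divide `N`, the single remainder
#' pool is smaller and is kept in the same stratum.
#'
#' @param N number of individuals.
#' @param pool_size pool size.
#' @param seed optional seed.
#' @return List of disjoint integer vectors covering `1..N`.
#' @export
assign_pools <- function(N, pool_size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(N)
  unname(split(perm, ceiling(seq_len(N) / pool_size)))
}

#' Misclassified test response
#'
#' Draws the observed outcome of a test given the true pool status:
#' positive with probability `se` when the pool is truly positive, and with
#' probability `1 - sp` when it is truly negative (vectorized).
#'
#' @param z_true binary vector of true pool statuses.
#' @param se,sp assay sensitivity and specificity in (0, 1].
#' @return Binary vector of observed outcomes.
#' @export
test_response <- function(z_true, se, sp) {
  stopifnot(all(se > 0 & se <= 1), all(sp > 0 & sp <= 1))
  p <- ifelse(z_true == 1L, se, 1 - sp)
  rbinom(length(z_true), 1, p)
}

# Distinct sub-streams per protocol, so IT/MPT/DT runs on one master seed
# share the identical population but use independent test noise.
protocol_seed <- function(seed, protocol) {
  if (is.null(seed)) return(NULL)
  seed + 1000003L * match(protocol, c("IT", "MPT", "DT"))
}

#' Apply a group testing protocol to a simulated population
#'
#' Generates observed group testing data from true statuses:
#' \describe{
#'   \item{IT}{one singleton-pool test per individual (stratum 1).}
#'   \item{MPT}{one test per master pool (stratum 1), no follow-up.}
#'   \item{DT}{master pool tests (stratum 1), then every member of each
#'     master pool whose observed outcome is positive is retested
#'     individually (stratum 2).}
#' }
#' Retesting under DT is triggered by the observed master-pool outcome, not
#' the true pool status.  Stratum-specific accuracies come from
#' `design$accuracy_truth`.
#'
#' @param truth a [simulate_statuses()] result.
#' @param design the matching [sim_design()].
#' @return A [group_testing_data()] object.
#' @export
run_protocol <- function(truth, design) {
  seed <- protocol_seed(design$seed, design$protocol)
  if (!is.null(seed)) set.seed(seed)
  acc <- design$accuracy_truth
  N <- length(truth$y_true)

  if (design$protocol == "IT") {
    pools <- as.list(seq_len(N))
    Z <- test_response(truth$y_true, acc$se[1], acc$sp[1])
    return(group_testing_data(Z, pools, rep(1L, N), truth$X))
  }

  pools <- assign_pools(N, design$pool_size)
  z_true <- vapply(pools, function(p) pool_true_status(truth$y_true, p), 0L)
  Z <- test_response(z_true, acc$se[1], acc$sp[1])
  stratum <- rep(1L, length(pools))

  if (design$protocol == "DT") {
    for (j in which(Z == 1L)) {
      members <- pools[[j]]
      z_re <- test_response(truth$y_true[members], acc$se[2], acc$sp[2])
      pools <- c(pools, as.list(members))
      Z <- c(Z, z_re)
      stratum <- c(stratum, rep(2L, length(members)))
    }
  }
  group_testing_data(Z, pools, stratum, truth$X)
}

#' Simulate a complete group testing data set
#'
#' One-call wrapper: builds the design, simulates covariates and statuses,
#' and applies the testing protocol.
#'
#' @inheritParams sim_design
#' @return A list with `data` ([group_testing_data()]), `truth`
#'   ([simulate_statuses()] result) and `design`.
#' @export
#' @examples
#' sim <- gt_simulate("M3", N = 200, protocol = "DT", seed = 1)
#' sim$data
gt_simulate <- function(model = "M1", N = 5000, pool_size = 4,
                        protocol = "DT",
                        accuracy_truth = assay_accuracy(c(0.95, 0.98),
                                                        c(0.98, 0.99)),
                        seed = NULL, f = NULL) {
  design <- sim_design(model, N, pool_size, protocol, accuracy_truth, seed, f)
  truth <- simulate_statuses(design)
  data <- run_protocol(truth, design)
  list(data = data, truth = truth, design = design)
}
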