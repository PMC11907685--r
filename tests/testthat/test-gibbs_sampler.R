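status_conditional_cpp <- function(data, se, sp, eta, y) {
  status_probability(data, assay_accuracy(se, sp), eta, y)
}

# Status-only Gibbs chain (internal sampler entry point), checked against
# exhaustive enumeration of the joint.
status_chain_cpp <- function(data, se, sp, eta, y0, n_sweeps) {
  csr <- gtbart:::pool_csr(data)
  gtbart:::cpp_status_chain(data$Z, csr$start, csr$idx, data$stratum - 1L,
                            data$L, se, sp, eta, as.integer(y0),
                            as.integer(n_sweeps))
}

test_that("latent-status full conditional matches enumeration to 1e-12", {
  # N = 3, one pool, arbitrary accuracies and eta
  X <- matrix(runif(6), 3, 2)
  data <- group_testing_data(Z = 1L, pools = list(1:3), stratum = 1L, X = X)
  se <- 0.93; sp <- 0.96
  eta <- c(-0.4, 0.2, -1.1)
  joint <- enumerate_status_joint(data, se, sp, eta)
  for (y23 in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    for (y1 in 0:1) {
      y <- c(y1, y23)
      mask0 <- 1 + sum(c(0, y23) * 2^(0:2))   # y1 = 0
      mask1 <- 1 + sum(c(1, y23) * 2^(0:2))   # y1 = 1
      oracle <- joint[mask1] / (joint[mask0] + joint[mask1])
      p <- status_conditional_cpp(data, se, sp, eta, y)
      expect_equal(p[1], oracle, tolerance = 1e-12)
    }
  }
})

test_that("individuals tested in no pool fall back to the probit prior", {
  X <- matrix(runif(6), 3, 2)
  data <- group_testing_data(Z = 1L, pools = list(1:2), stratum = 1L, X = X)
  eta <- c(0.3, -0.2, 0.7)
  p <- status_conditional_cpp(data, 0.95, 0.98, eta, c(0L, 0L, 0L))
  expect_equal(p[3], pnorm(0.7), tolerance = 1e-12)
})

test_that("a perfect individual test pins the status", {
  X <- matrix(runif(4), 2, 2)
  data <- group_testing_data(Z = c(1L, 0L), pools = list(1, 2),
                             stratum = c(1L, 1L), X = X)
  p <- status_conditional_cpp(data, 1 - 1e-12, 1 - 1e-12, c(0, 0), c(0L, 0L))
  expect_gt(p[1], 1 - 1e-6)
  expect_lt(p[2], 1e-6)
})

test_that("status Gibbs chain matches exhaustive enumeration (tiny Dorfman)", {
  # N = 4: one master pool + retests of individuals 1 and 2
  data <- tiny_dorfman_data(Z_master = 1L, Z_retests = c(1L, 0L),
                            retested = 1:2)
  se <- c(0.9, 0.85); sp <- c(0.92, 0.95)
  eta <- c(-0.3, -0.8, 0.1, -0.5)
  exact <- enumerate_status_joint(data, se, sp, eta)
  set.seed(99)
  chain <- status_chain_cpp(data, se, sp, eta, y0 = c(1L, 0L, 0L, 0L),
                            n_sweeps = 1e5)
  for (k in seq_along(exact)) {
    if (exact[k] < 5e-4) next
    ind <- chain$trace == (k - 1L)
    expect_lt(abs(mean(ind) - exact[k]), 3 * batch_se(ind) + 1e-9)
  }
  # total variation against the exact law is small
  freq <- tabulate(chain$trace + 1L, nbins = length(exact)) / 1e5
  expect_lt(0.5 * sum(abs(freq - exact)), 0.01)
})

test_that("with near-perfect assays and all tests negative, positives vanish", {
  data <- tiny_dorfman_data(Z_master = 0L, Z_retests = integer(0),
                            retested = integer(0))
  exact <- enumerate_status_joint(data, 0.9999, 0.9999, rep(-0.2, 4))
  expect_lt(1 - exact[1], 1e-2)     # configuration "all negative"
  set.seed(7)
  chain <- status_chain_cpp(data, 0.9999, 0.9999, rep(-0.2, 4),
                            y0 = rep(0L, 4), n_sweeps = 2e4)
  expect_lt(mean(chain$trace != 0L), 1e-2)
})

test_that("a positive retest never lowers the sampled-positive frequency", {
  # monotonicity, checked by enumeration: add a positive individual retest
  base <- tiny_dorfman_data(Z_master = 1L, Z_retests = 0L, retested = 2)
  plus <- tiny_dorfman_data(Z_master = 1L, Z_retests = c(0L, 1L),
                            retested = c(2, 1))
  se <- c(0.9, 0.9); sp <- c(0.95, 0.95)
  eta <- rep(-0.5, 4)
  marg1 <- function(joint) {
    y1 <- as.integer(intToBits(seq_along(joint) - 1L))[seq(1, 32 * length(joint), 32)]
    sum(joint[y1 == 1])
  }
  expect_gt(marg1(enumerate_status_joint(plus, se, sp, eta)),
            marg1(enumerate_status_joint(base, se, sp, eta)))
})

test_that("one-sided truncated normal draws are correct and tail-stable", {
  set.seed(12)
  n <- 1e5
  pos <- gtbart:::cpp_rtnorm(rep(0, n), rep(TRUE, n))
  expect_true(all(pos > 0))
  half_mean <- sqrt(2 / pi)
  half_sd <- sqrt(1 - 2 / pi)
  expect_lt(abs(mean(pos) - half_mean), 3 * half_sd / sqrt(n))
  # deep negative mean: compare with quadrature of the truncated density
  neg3 <- gtbart:::cpp_rtnorm(rep(-3, n), rep(TRUE, n))
  expect_true(all(neg3 > 0))
  m_oracle <- integrate(function(x) x * dnorm(x, -3) / pnorm(3, lower.tail = FALSE),
                        0, Inf, rel.tol = 1e-12)$value
  expect_lt(abs(mean(neg3) - m_oracle), 3 * sd(neg3) / sqrt(n))
  # no NaN/Inf out to |eta| = 10, both truncation sides
  extreme <- gtbart:::cpp_rtnorm(rep(c(-10, 10), 50), rep(c(TRUE, FALSE), 50))
  expect_true(all(is.finite(extreme)))
  expect_true(all(extreme[seq(1, 100, 2)] > 0))
  expect_true(all(extreme[seq(2, 100, 2)] <= 0))
})

test_that("accuracy full-conditional counts follow the printed beta updates", {
  # direct tally per the update: a_e* = a_e + sum Z_j Ztilde_j etc.
  data <- tiny_dorfman_data(Z_master = 1L, Z_retests = c(1L, 0L, 1L),
                            retested = c(1, 2, 3))
  y <- c(1L, 1L, 0L, 0L)
  zt <- vapply(data$pools, function(p) pool_true_status(y, p), 0L)
  for (l in 1:2) {
    j <- data$stratum == l
    a_star <- 1L + sum(data$Z[j] * zt[j])
    b_star <- 1L + sum((1L - data$Z[j]) * zt[j])
    # counting identity: growth of the Se posterior equals truly positive tests
    expect_identical(a_star + b_star - 2L, sum(zt[j] == 1L))
  }
  # stratum 2 (retests of 1,2,3 with y = 1,1,0): (Z, Ztilde) = (1,1),(0,1),(1,0)
  j2 <- data$stratum == 2L
  expect_equal(1 + sum(data$Z[j2] * zt[j2]), 2)           # a_e* = 2
  expect_equal(1 + sum((1 - data$Z[j2]) * zt[j2]), 2)     # b_e* = 2
  expect_equal(1 + sum((1 - data$Z[j2]) * (1 - zt[j2])), 1)
  expect_equal(1 + sum(data$Z[j2] * (1 - zt[j2])), 2)
})

test_that("known strata are never touched by the sampler", {
  sim <- gt_simulate("M2", N = 120, protocol = "DT", seed = 21)
  acc <- assay_accuracy(c(0.95, 0.98), c(0.98, 0.99),
                        known = c(TRUE, FALSE))
  fit <- gt_bart(sim$data, acc, K = 5, n_burn = 30, n_keep = 40, seed = 3)
  expect_true(all(fit$se_draws[, 1] == 0.95))
  expect_true(all(fit$sp_draws[, 1] == 0.98))
  expect_gt(var(fit$se_draws[, 2]), 0)
})

test_that("run_chain is bit-reproducible under a seed and caches consistently", {
  sim <- gt_simulate("M3", N = 150, protocol = "DT", seed = 31)
  acc <- assay_accuracy(c(0.95, 0.98), c(0.98, 0.99))
  f1 <- gt_bart(sim$data, acc, K = 8, n_burn = 40, n_keep = 30, seed = 77,
                store_trees = TRUE)
  f2 <- gt_bart(sim$data, acc, K = 8, n_burn = 40, n_keep = 30, seed = 77,
                store_trees = TRUE)
  expect_identical(f1$se_draws, f2$se_draws)
  expect_identical(f1$eta_draws, f2$eta_draws)
  expect_identical(f1$trees, f2$trees)
  # stored eta draws equal a fresh evaluation of the stored ensembles:
  # the incrementally maintained eta cache never drifts from the trees
  for (s in c(1, 17, 30)) {
    eta_s <- ensemble_evaluate(f1$trees[[s]], sim$data$X)
    expect_equal(unname(f1$eta_draws[s, ]), eta_s, tolerance = 1e-10)
  }
})

test_that("split counts count interior nodes of the stored ensembles", {
  sim <- gt_simulate("M1", N = 200, protocol = "DT", seed = 41)
  acc <- assay_accuracy(c(0.95, 0.98), c(0.98, 0.99), known = TRUE)
  fit <- gt_bart(sim$data, acc, K = 6, n_burn = 50, n_keep = 25, seed = 5,
                 store_trees = TRUE)
  for (s in c(3, 25)) {
    counts <- integer(3)
    for (tr in fit$trees[[s]]) {
      splits <- tr$var[tr$var > 0]
      counts <- counts + tabulate(splits, nbins = 3)
    }
    expect_identical(unname(fit$split_counts[s, ]), counts)
  }
})

test_that("M2/DT fit recovers the probability surface (rank correlation)", {
  sim <- gt_simulate("M2", N = 1000, protocol = "DT", seed = 51)
  acc <- assay_accuracy(c(0.95, 0.98), c(0.98, 0.99), known = TRUE)
  fit <- gt_bart(sim$data, acc, K = 20, n_burn = 400, n_keep = 400,
                 seed = 6, store_eta = FALSE)
  expect_gt(cor(fit$prob_train_mean, sim$truth$p_true, method = "spearman"),
            0.5)
})
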