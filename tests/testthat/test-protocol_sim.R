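test_that("true_f reproduces the stated surfaces", {
  expect_equal(true_f("M1", c(0.5, 3, 1)), sin(0.5 * pi) - 1.25)
  expect_equal(true_f("M1", c(0.5, 3, 1)), -0.25)
  expect_equal(true_f("M2", c(0, 0, 0)), -0.85)
  expect_equal(true_f("M2", c(1, 2, 1)),
               -0.85 + 0.55 * 1 - 1.25 * 2 - 0.35 * 1)
  # with the binary covariate off, M3 drops to -sin(x1/3) for any x2
  for (x1 in c(0.3, 4, 9.7))
    expect_equal(true_f("M3", c(x1, runif(1, 0, 10), 0)), -sin(x1 / 3))
  expect_equal(true_f("M3", c(2, 5, 1)), -sin(2 / 3) - 2 + 1)
  expect_equal(true_f("custom", matrix(1:6, 2), f = function(X) X[, 1] * 2),
               c(2, 4))
  expect_error(true_f("M9", c(1, 1, 1)), "unknown model")
})

test_that("simulate_statuses draws the stated covariates and statuses", {
  design <- sim_design("M2", N = 1e5, seed = 7)
  truth <- simulate_statuses(design)
  expect_true(all(truth$X[, 1] > 0 & truth$X[, 1] < 10))
  expect_true(all(truth$X[, 3] %in% 0:1))
  expect_equal(truth$p_true, pnorm(true_f("M2", truth$X)))
  # law of large numbers: empirical prevalence within 3 MC SEs of E[Phi(f)]
  p_bar <- mean(truth$p_true)
  se_mc <- sqrt(p_bar * (1 - p_bar) / design$N)
  expect_lt(abs(mean(truth$y_true) - p_bar), 3 * se_mc)
  # determinism under the seed
  truth2 <- simulate_statuses(design)
  expect_identical(truth, truth2)
})

test_that("assign_pools partitions 1..N with one short remainder pool", {
  p8 <- assign_pools(8, 4, seed = 1)
  expect_length(p8, 2)
  expect_setequal(unlist(p8), 1:8)
  p9 <- assign_pools(9, 4, seed = 1)
  expect_identical(sort(lengths(p9), decreasing = TRUE), c(4L, 4L, 1L))
  expect_setequal(unlist(p9), 1:9)
  expect_identical(anyDuplicated(unlist(p9)), 0L)
})

test_that("test_response follows the misclassification model", {
  set.seed(11)
  expect_true(all(test_response(rep(1, 50), se = 1, sp = 0.5) == 1))
  expect_true(all(test_response(rep(0, 50), se = 0.5, sp = 1) == 0))
  n <- 1e5
  fp <- mean(test_response(rep(0, n), se = 0.95, sp = 0.98))
  expect_lt(abs(fp - 0.02), 3 * sqrt(0.02 * 0.98 / n))
  tp <- mean(test_response(rep(1, n), se = 0.95, sp = 0.98))
  expect_lt(abs(tp - 0.95), 3 * sqrt(0.95 * 0.05 / n))
})

test_that("Dorfman testing resolves observed-positive pools individually", {
  # near-perfect assays so the protocol trace is deterministic
  acc <- assay_accuracy(c(1 - 1e-12, 1 - 1e-12), c(1 - 1e-12, 1 - 1e-12))
  design <- sim_design("M1", N = 8, pool_size = 4, protocol = "DT",
                       accuracy_truth = acc, seed = 3)
  truth <- simulate_statuses(design)
  truth$y_true <- c(1, 0, 0, 0, 0, 0, 0, 0)
  data <- run_protocol(truth, design)
  expect_identical(data$J, 6L)                     # 2 master pools + 4 retests
  expect_identical(data$stratum, c(1L, 1L, 2L, 2L, 2L, 2L))
  expect_identical(sum(data$Z[data$stratum == 1L]), 1L)
  pos_pool <- data$pools[[which(data$Z == 1L & data$stratum == 1L)]]
  expect_setequal(unlist(data$pools[data$stratum == 2L]), pos_pool)
  expect_identical(sum(data$Z[data$stratum == 2L]), 1L)   # only individual 1
  retest_of_1 <- data$stratum == 2L & vapply(data$pools, identical, NA, 1L)
  expect_identical(unique(data$Z[retest_of_1]), 1L)

  # all-negative population: no resolution stage
  truth$y_true <- rep(0L, 8)
  data0 <- run_protocol(truth, design)
  expect_identical(data0$J, 2L)
  expect_true(all(data0$Z == 0L))
})

test_that("MPT test count is fixed by the pooling, IT by N", {
  acc <- assay_accuracy(c(0.95, 0.98), c(0.98, 0.99))
  sim <- gt_simulate("M2", N = 5000, pool_size = 4, protocol = "MPT",
                     accuracy_truth = acc, seed = 5)
  expect_identical(sim$data$J, 1250L)
  expect_true(all(lengths(sim$data$pools) == 4L))
  it <- gt_simulate("M2", N = 100, protocol = "IT", accuracy_truth = acc,
                    seed = 5)
  expect_identical(it$data$J, 100L)
  expect_true(all(lengths(it$data$pools) == 1L))
})

test_that("DT test count identity and generated data always validate", {
  for (seed in 1:5) {
    sim <- gt_simulate("M3", N = 203, pool_size = 4, protocol = "DT",
                       seed = seed)
    expect_identical(validate_group_data(sim$data), character(0))
    n_master <- sum(sim$data$stratum == 1L)
    expect_identical(n_master, as.integer(ceiling(203 / 4)))
    pos_masters <- which(sim$data$Z == 1L & sim$data$stratum == 1L)
    expect_identical(sum(sim$data$stratum == 2L),
                     length(unlist(sim$data$pools[pos_masters])))
  }
})

test_that("one master seed yields identical populations across protocols", {
  acc <- assay_accuracy(c(0.95, 0.98), c(0.98, 0.99))
  a <- gt_simulate("M2", N = 400, protocol = "MPT", accuracy_truth = acc,
                   seed = 9)
  b <- gt_simulate("M2", N = 400, protocol = "DT", accuracy_truth = acc,
                   seed = 9)
  expect_identical(a$truth, b$truth)
  expect_identical(a$data$X, b$data$X)
})
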