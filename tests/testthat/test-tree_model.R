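test_that("tree evaluation routes the worked two-tree example as published", {
  muA <- c(0.11, 0.22, 0.33)   # leaves mu11, mu21, mu31 of the first tree
  muB <- c(-0.4, 0.15, 0.27)   # leaves mu12, mu22, mu32 of the second
  tA <- example_tree_A(muA)
  tB <- example_tree_B(muB)
  X <- example_covariates()
  expect_equal(tree_evaluate(tA, X), muA[c(3, 2, 1, 2, 3)])
  expect_equal(tree_evaluate(tB, X), muB[c(1, 3, 2, 1, 3)])
  eta <- ensemble_evaluate(list(tA, tB), X)
  expect_equal(eta[1], muA[3] + muB[1])     # individual 1: mu31 + mu12
  expect_equal(eta[5], muA[3] + muB[3])     # individual 5: mu31 + mu32
})

test_that("stumps and irrelevant covariates behave as step functions require", {
  X <- matrix(runif(30), 10, 3)
  expect_equal(tree_evaluate(tree_stump(0.3), X), rep(0.3, 10))
  # K stumps sum to the sum of their leaves everywhere
  stumps <- lapply(c(0.1, -0.2, 0.4), tree_stump)
  expect_equal(ensemble_evaluate(stumps, X), rep(0.3, 10))
  # changing a covariate unused by any rule never changes the output
  tA <- example_tree_A()
  X1 <- example_covariates()
  X2 <- X1; X2[, 3] <- X2[, 3] + 1000
  expect_equal(tree_evaluate(tA, X1), tree_evaluate(tA, X2))
})

test_that("tree_log_prior matches the depth-penalty formula", {
  cuts <- make_cutpoints(example_covariates())
  expect_equal(tree_log_prior(tree_stump(), cuts), log(0.05))
  # interior-node probability at depth 1 with defaults
  expect_equal(0.95 * (1 + 1)^-2, 0.2375)
  # a depth-1 tree: root split + two leaves at depth 1, uniform rule choice
  t1 <- data.frame(node = 1:3, parent = c(0L, 1L, 1L), left = c(2L, 0L, 0L),
                   right = c(3L, 0L, 0L), var = c(1L, 0L, 0L),
                   cutoff = c(41, NA, NA), mu = c(NA, 0.1, 0.2))
  expect_equal(tree_log_prior(t1, cuts),
               log(0.95) + log(1 / 3) + log(1 / 5) + 2 * log(1 - 0.2375))
  # alpha -> 0: any split becomes impossible
  expect_lt(tree_log_prior(t1, cuts, alpha = 1e-12), log(1e-11))
})

test_that("leaf_posterior matches the conjugate form and quadrature", {
  expect_equal(leaf_posterior(numeric(0), 0.5),
               c(mean = 0, variance = 0.25))
  expect_equal(leaf_posterior(1, 1), c(mean = 0.5, variance = 0.5))
  set.seed(5)
  for (rep in 1:5) {
    r <- rnorm(sample(1:6, 1), sd = 1.3)
    s <- runif(1, 0.2, 2)
    post <- leaf_posterior(r, s)
    dens <- function(mu) vapply(mu, function(m)
      prod(dnorm(r - m)) * dnorm(m, 0, s), 0)
    z <- integrate(dens, -Inf, Inf, rel.tol = 1e-12)$value
    m1 <- integrate(function(mu) mu * dens(mu), -Inf, Inf,
                    rel.tol = 1e-12)$value / z
    m2 <- integrate(function(mu) mu^2 * dens(mu), -Inf, Inf,
                    rel.tol = 1e-12)$value / z
    expect_equal(unname(post[1]), m1, tolerance = 1e-8)
    expect_equal(unname(post[2]), m2 - m1^2, tolerance = 1e-8)
  }
})

test_that("integrated likelihood matches closed form and quadrature", {
  stump <- tree_stump()
  X1 <- matrix(0.5, 1, 1)
  expect_equal(tree_integrated_loglik(stump, X1, 0, 1),
               -0.5 * log(2 * pi) - 0.5 * log(2))
  # quadrature oracle on 2-leaf trees with <= 5 observations
  t1 <- data.frame(node = 1:3, parent = c(0L, 1L, 1L), left = c(2L, 0L, 0L),
                   right = c(3L, 0L, 0L), var = c(1L, 0L, 0L),
                   cutoff = c(0.5, NA, NA), mu = c(NA, 0, 0))
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    X <- matrix(runif(n), n, 1)
    r <- rnorm(n)
    s <- runif(1, 0.3, 1.5)
    left <- X[, 1] <= 0.5
    oracle <- log(leaf_marginal_quadrature(r[left], s)) +
      log(leaf_marginal_quadrature(r[!left], s))
    expect_equal(tree_integrated_loglik(t1, X, r, s), oracle,
                 tolerance = 1e-6)
  }
  # an empty leaf contributes nothing
  Xall <- matrix(runif(4, 0.6, 1), 4, 1)  # all route right
  r <- rnorm(4)
  expect_equal(tree_integrated_loglik(t1, Xall, r, 0.7),
               tree_integrated_loglik(stump, Xall, r, 0.7))
})

test_that("GROW from a stump yields a depth-1 tree and PRUNE inverts it", {
  cuts <- list(c(0.3, 0.6))
  X <- matrix(c(0.2, 0.5, 0.9), 3, 1)
  set.seed(2)
  grown <- NULL
  for (i in 1:50) {   # only GROW is available from a stump
    step <- tree_mh_step(tree_stump(), cuts, X, rnorm(3), 0.5)
    expect_identical(step$move, "grow")
    if (step$accepted) { grown <- step$tree; break }
  }
  expect_false(is.null(grown))
  expect_identical(nrow(grown), 3L)
  expect_identical(sum(grown$var > 0), 1L)
  # keep pruning: eventually returns to a stump
  tr <- grown
  for (i in 1:200) {
    step <- tree_mh_step(tr, cuts, X, rnorm(3), 0.5)
    tr <- step$tree
    if (nrow(tr) == 1) break
  }
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$var, 0L)
})

test_that("GROW acceptance ratio matches the hand-computed quantity", {
  # stump, one covariate with a single cutpoint, equal residuals:
  # every ingredient of the MH ratio has a closed form
  cuts <- list(0.5)
  X <- matrix(c(0.25, 0.75), 2, 1)
  r <- c(0.8, 0.8)
  s <- 0.6
  alpha <- 0.95; beta <- 2
  ll <- function(groups) sum(vapply(groups, function(g) {
    n <- length(g)
    -n / 2 * log(2 * pi) - 0.5 * log(1 + n * s^2) - 0.5 * sum(g^2) +
      0.5 * s^2 * sum(g)^2 / (1 + n * s^2)
  }, 0))
  d_loglik <- ll(list(r[1], r[2])) - ll(list(r))
  p_split0 <- alpha
  p_split1 <- alpha / 4
  d_logprior <- log(p_split0) + log(1) + 2 * log(1 - p_split1) -
    log(1 - p_split0)
  # stump: GROW certain; depth-1 tree: GROW/PRUNE/CHANGE available -> prune
  # probability 0.25/0.9; one nog node, one leaf-choice, one rule
  d_logq <- log(0.25 / 0.9) - log(1)
  expected <- d_loglik + d_logprior + d_logq
  set.seed(4)
  step <- tree_mh_step(tree_stump(), cuts, X, r, s, alpha = alpha,
                       beta = beta)
  expect_identical(step$move, "grow")
  expect_equal(step$log_alpha, expected, tolerance = 1e-12)
})

test_that("prior-only MH chain reproduces the enumerated tree prior", {
  # constant likelihood (no observations, min_leaf = 0): the chain's
  # stationary law is exactly the tree prior; compare visit frequencies of
  # the stump and each depth-1 rule against their closed-form probabilities
  cuts <- list(c(2, 5, 8))
  X <- matrix(numeric(0), 0, 1)
  alpha <- 0.5; beta <- 1.5
  signature <- function(tr) {
    if (nrow(tr) == 1) return("stump")
    if (nrow(tr) == 3) return(paste0("d1cut", tr$cutoff[1]))
    "deeper"
  }
  set.seed(31)
  n_iter <- 20000
  tr <- tree_stump()
  sig <- character(n_iter)
  for (i in seq_len(n_iter)) {
    tr <- tree_mh_step(tr, cuts, X, numeric(0), 0.8, alpha = alpha,
                       beta = beta, min_leaf = 0)$tree
    sig[i] <- signature(tr)
  }
  p_d1 <- alpha * (1 + 1)^-beta
  p_stump <- 1 - alpha
  p_one_d1 <- alpha * (1 / 3) * (1 - p_d1)^2
  freq <- function(s) mean(sig == s)
  expect_lt(abs(freq("stump") - p_stump),
            3 * batch_se(sig == "stump") + 1e-9)
  for (cut in c(2, 5, 8)) {
    key <- paste0("d1cut", cut)
    expect_lt(abs(freq(key) - p_one_d1), 3 * batch_se(sig == key) + 1e-9)
  }
})

test_that("trees serialize to JSON and back", {
  trees <- list(example_tree_A(), example_tree_B(), tree_stump(0.4))
  path <- tempfile(fileext = ".json")
  write_trees_json(trees, path)
  back <- read_trees_json(path)
  for (k in seq_along(trees))
    expect_equal(as.data.frame(back[[k]]), as.data.frame(trees[[k]]))
})
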