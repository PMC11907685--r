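# Independent oracles used across the suite.  Everything here is deliberately
# brute-force (enumeration, quadrature) and shares no code with the sampler.

# Exact joint posterior over all 2^N status configurations given the observed
# tests, by direct evaluation of the misclassification likelihood times the
# probit prior, with eta, Se, Sp fixed.  Configuration k (1-based) encodes
# statuses as the bits of k-1 (individual i = bit i-1), matching the bitmask
# trace returned by the status chain.
enumerate_status_joint <- function(data, se, sp, eta) {
  N <- data$N
  n_cfg <- 2^N
  logw <- numeric(n_cfg)
  lp1 <- pnorm(eta, log.p = TRUE)
  lp0 <- pnorm(eta, lower.tail = FALSE, log.p = TRUE)
  for (k in seq_len(n_cfg)) {
    y <- as.integer(intToBits(k - 1))[1:N]
    lp <- sum(ifelse(y == 1, lp1, lp0))
    for (j in seq_len(data$J)) {
      zt <- any(y[data$pools[[j]]] == 1)
      l <- data$stratum[j]
      pz <- if (zt) {
        if (data$Z[j] == 1) se[l] else 1 - se[l]
      } else {
        if (data$Z[j] == 1) 1 - sp[l] else sp[l]
      }
      lp <- lp + log(pz)
    }
    logw[k] <- lp
  }
  w <- exp(logw - max(logw))
  w / sum(w)
}

# Monte-Carlo standard error of occupation frequencies from a dependent
# chain, by batch means.
batch_se <- function(ind, n_batch = 100) {
  n <- length(ind)
  b <- split(ind, rep(seq_len(n_batch), each = ceiling(n / n_batch))[1:n])
  means <- vapply(b, mean, 0)
  sd(means) / sqrt(length(means))
}

# The two trees of the worked sum-of-trees example: tree A splits on x1 then
# x2 (leaves muA1, muA2, muA3); tree B splits on x3 then x2 (leaves muB1,
# muB2, muB3).  Cutoffs chosen so the five example individuals route to the
# published terminal nodes.
example_tree_A <- function(mu = c(0.1, 0.2, 0.3)) {
  data.frame(
    node = 1:5,
    parent = c(0L, 1L, 1L, 2L, 2L),
    left = c(2L, 4L, 0L, 0L, 0L),
    right = c(3L, 5L, 0L, 0L, 0L),
    var = c(1L, 2L, 0L, 0L, 0L),
    cutoff = c(45, 120, NA, NA, NA),
    mu = c(NA, NA, mu[3], mu[1], mu[2]))
}

example_tree_B <- function(mu = c(-0.1, 0.15, 0.25)) {
  data.frame(
    node = 1:5,
    parent = c(0L, 1L, 1L, 3L, 3L),
    left = c(2L, 0L, 4L, 0L, 0L),
    right = c(3L, 0L, 5L, 0L, 0L),
    var = c(3L, 0L, 2L, 0L, 0L),
    cutoff = c(-5, NA, 120, NA, NA),
    mu = c(NA, mu[1], NA, mu[2], mu[3]))
}

example_covariates <- function() {
  matrix(c(56, 110, -13,
           27, 173, -3,
           41, 94, 5,
           30, 213, -9,
           48, 168, 39), ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x1", "x2", "x3")))
}

# Quadrature marginal likelihood of residuals in one leaf: integrates the
# unit-variance normal likelihood against the N(0, sigma_mu^2) leaf prior.
leaf_marginal_quadrature <- function(r, sigma_mu) {
  if (length(r) == 0) return(1)
  f <- function(mu)
    vapply(mu, function(m) prod(dnorm(r - m)) * dnorm(m, 0, sigma_mu), 0)
  integrate(f, -Inf, Inf, rel.tol = 1e-12)$value
}

# A small fixed Dorfman-style data set used by several tests: one master
# pool of 4 (stratum 1) plus individual retests (stratum 2).
tiny_dorfman_data <- function(Z_master, Z_retests, retested = seq_along(Z_retests),
                              N = 4) {
  X <- matrix(seq_len(N * 2) / 10, N, 2)
  pools <- c(list(1:N), as.list(retested))
  Z <- c(Z_master, Z_retests)
  stratum <- c(1L, rep(2L, length(retested)))
  group_testing_data(Z, pools, stratum, X)
}
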