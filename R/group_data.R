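#' Group testing data
#'
#' Container for observed group testing data: one binary outcome per test,
#' the index set of individuals contributing to each test's pool, a stratum
#' label per test (tests in a stratum share one sensitivity/specificity
#' pair), and the individual-level covariate matrix.  Pools may overlap and
#' an individual may appear in several tests (e.g., Dorfman retests).
#'
#' @param Z binary vector of observed test outcomes, length `J`.
#' @param pools list of `J` integer vectors; `pools[[j]]` holds the 1-based
#'   indices of the individuals contributing to test `j`.
#' @param stratum integer vector of stratum labels in `1..L`, length `J`.
#'   Strata are opaque labels; mapping assay/specimen/pool-size factors to
#'   strata is the caller's responsibility.
#' @param X numeric covariate matrix with one row per individual.
#'
#' @return An object of class `gt_data` with elements `N`, `J`, `L`, `Z`,
#'   `pools`, `stratum`, `X`.
#' @seealso [validate_group_data()], [gt_simulate()], [gt_bart()]
#' @export
#' @examples
#' X <- matrix(runif(8), 4, 2)
#' d <- group_testing_data(Z = c(1, 0), pools = list(1:2, 3:4),
#'                         stratum = c(1, 1), X = X)
#' validate_group_data(d)
group_testing_data <- function(Z, pools, stratum, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(is.list(pools), length(Z) == length(pools),
            length(stratum) == length(Z))
  structure(list(
    N = nrow(X), J = length(Z), L = max(as.integer(stratum), 1L),
    Z = as.integer(Z), pools = lapply(pools, as.integer),
    stratum = as.integer(stratum), X = X
  ), class = "gt_data")
}

#' Check group testing data invariants
#'
#' Reports (rather than signals) violations of the data-model invariants:
#' pools must be non-empty and reference individuals in `1..N`, outcomes must
#' be 0/1, and stratum labels must lie in `1..L` with no empty stratum below
#' the maximum label.
#'
#' @param data a [group_testing_data()] object.
#' @return A character vector of violation descriptions, each naming the
#'   offending test or individual; `character(0)` if the data are
#'   well-formed.
#' @export
validate_group_data <- function(data) {
  out <- character(0)
  for (j in seq_len(data$J)) {
    p <- data$pools[[j]]
    if (length(p) == 0)
      out <- c(out, sprintf("test %d: empty pool", j))
    else if (anyNA(p) || any(p < 1L) || any(p > data$N))
      out <- c(out, sprintf("test %d: pool references individuals outside 1..%d",
                            j, data$N))
    if (anyDuplicated(p))
      out <- c(out, sprintf("test %d: duplicated individual in pool", j))
  }
  bad_z <- which(!(data$Z %in% c(0L, 1L)))
  for (j in bad_z)
    out <- c(out, sprintf("test %d: outcome %s is not binary", j, data$Z[j]))
  bad_s <- which(is.na(data$stratum) | data$stratum < 1L)
  for (j in bad_s)
    out <- c(out, sprintf("test %d: stratum label %s out of range", j,
                          data$stratum[j]))
  if (data$N < 1L) out <- c(out, "no individuals")
  out
}

#' @export
print.gt_data <- function(x, ...) {
  cat(sprintf(
    "Group testing data: %d individuals, %d tests, %d strata, %d covariates\n",
    x$N, x$J, x$L, ncol(x$X)))
  sizes <- lengths(x$pools)
  cat(sprintf("  pool sizes %d-%d; %d positive tests\n",
              min(sizes), max(sizes), sum(x$Z)))
  invisible(x)
}

#' True status of a pool
#'
#' A pool is truly positive iff at least one contributing individual is truly
#' positive: \eqn{\tilde Z_j = I(\sum_{i \in \mathcal{P}_j} \tilde Y_i > 0)}.
#'
#' @param y_tilde binary vector of individual true statuses.
#' @param pool integer vector of 1-based member indices (non-empty).
#' @return 0 or 1.
#' @export
pool_true_status <- function(y_tilde, pool) {
  if (length(pool) == 0) stop("malformed data: empty pool")
  if (any(pool < 1L) || any(pool > length(y_tilde)))
    stop("pool references individuals outside the status vector")
  as.integer(any(y_tilde[pool] == 1L))
}

#' Assay accuracy parameters
#'
#' Per-stratum sensitivity/specificity values with known/unknown flags and
#' beta prior hyperparameters.  For a known stratum the values are held fixed
#' by the samplers; for an unknown stratum `se`/`sp` act as generating truth
#' in simulators and as initialization hints, and the posterior is updated
#' with conjugate beta draws
#' \eqn{Se(l) \sim beta(a_e(l), b_e(l))}, \eqn{Sp(l) \sim beta(a_p(l), b_p(l))}.
#'
#' @param se,sp numeric vectors in (0,1), length `L`.
#' @param known logical vector length `L` (recycled); `TRUE` means the
#'   stratum's accuracies are fixed, never updated by the sampler.
#' @param prior beta hyperparameters: either a length-4 vector
#'   `c(a_e, b_e, a_p, b_p)` recycled across strata, or an `L x 4` matrix.
#'   Defaults to uniform priors (all ones).
#' @return An object of class `gt_accuracy`.
#' @export
#' @examples
#' # Dorfman configuration: master pools and individual retests, unknown
#' assay_accuracy(se = c(0.95, 0.98), sp = c(0.98, 0.99), known = FALSE)
assay_accuracy <- function(se, sp, known = FALSE, prior = c(1, 1, 1, 1)) {
  L <- length(se)
  stopifnot(length(sp) == L, all(se > 0 & se < 1), all(sp > 0 & sp < 1))
  known <- rep_len(as.logical(known), L)
  if (is.matrix(prior)) {
    stopifnot(nrow(prior) == L, ncol(prior) == 4)
    hyper <- prior
  } else {
    stopifnot(length(prior) == 4)
    hyper <- matrix(prior, L, 4, byrow = TRUE)
  }
  if (any(hyper <= 0)) stop("beta hyperparameters must be strictly positive")
  colnames(hyper) <- c("a_e", "b_e", "a_p", "b_p")
  structure(list(L = L, se = as.numeric(se), sp = as.numeric(sp),
                 known = known, hyper = hyper),
            class = "gt_accuracy")
}

#' @export
print.gt_accuracy <- function(x, ...) {
  cat(sprintf("Assay accuracy (%d strata):\n", x$L))
  for (l in seq_len(x$L))
    cat(sprintf("  stratum %d: Se=%.3f Sp=%.3f [%s]\n", l, x$se[l], x$sp[l],
                if (x$known[l]) "known" else "estimated"))
  invisible(x)
}

# 0-based CSR representation of the pools, for the C++ samplers
pool_csr <- function(data) {
  idx <- unlist(data$pools, use.names = FALSE) - 1L
  list(start = c(0L, cumsum(lengths(data$pools))), idx = as.integer(idx))
}
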