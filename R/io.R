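#' Read and write group testing data sets
#'
#' The on-disk format (version 1) is a pair of CSV files:
#' `<prefix>_individuals.csv` with columns `individual_id, x1..xQ`, and
#' `<prefix>_tests.csv` with columns `test_id, stratum, outcome, members`,
#' where `members` is a colon-separated list of individual ids.  Explicit
#' ids make internal indexing an implementation detail; `write` then `read`
#' is the identity on all fields.
#'
#' @param data a [group_testing_data()] object.
#' @param prefix file path prefix (directories are created).
#' @return `write_gt_data()` returns `prefix` invisibly; `read_gt_data()`
#'   returns the reconstructed `gt_data` object.
#' @export
write_gt_data <- function(data, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  ind <- data.frame(individual_id = seq_len(data$N))
  ind <- cbind(ind, as.data.frame(data$X))
  write.csv(ind, paste0(prefix, "_individuals.csv"), row.names = FALSE)
  tests <- data.frame(
    test_id = seq_len(data$J), stratum = data$stratum, outcome = data$Z,
    members = vapply(data$pools, paste, "", collapse = ":"))
  write.csv(tests, paste0(prefix, "_tests.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_gt_data
#' @export
read_gt_data <- function(prefix) {
  ind_path <- paste0(prefix, "_individuals.csv")
  test_path <- paste0(prefix, "_tests.csv")
  for (p in c(ind_path, test_path))
    if (!file.exists(p)) stop("missing dataset file: ", p)
  ind <- read.csv(ind_path)
  if (names(ind)[1] != "individual_id")
    stop(ind_path, ": first column must be individual_id")
  if (anyDuplicated(ind$individual_id))
    stop(ind_path, ": duplicated individual_id")
  o <- order(ind$individual_id)
  if (!identical(as.integer(ind$individual_id[o]), seq_len(nrow(ind))))
    stop(ind_path, ": individual_id must enumerate 1..N")
  X <- as.matrix(ind[o, -1, drop = FALSE])
  rownames(X) <- NULL

  tests <- read.csv(test_path, colClasses = c(members = "character"))
  need <- c("test_id", "stratum", "outcome", "members")
  if (!all(need %in% names(tests)))
    stop(test_path, ": columns must include ", paste(need, collapse = ", "))
  if (anyDuplicated(tests$test_id)) stop(test_path, ": duplicated test_id")
  tests <- tests[order(tests$test_id), ]
  pools <- lapply(seq_len(nrow(tests)), function(j) {
    m <- tests$members[j]
    if (is.na(m) || !nzchar(m))
      stop(sprintf("%s: line %d: empty member list", test_path, j + 1L))
    ids <- suppressWarnings(as.integer(strsplit(m, ":", fixed = TRUE)[[1]]))
    if (anyNA(ids))
      stop(sprintf("%s: line %d: malformed members field", test_path, j + 1L))
    ids
  })
  group_testing_data(tests$outcome, pools, tests$stratum, X)
}

#' @rdname write_gt_data
#' @param truth a `gt_truth` object ([simulate_statuses()]).
#' @param path CSV path for the truth table
#'   (`individual_id, p_true, y_true`).
#' @export
write_gt_truth <- function(truth, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(individual_id = seq_along(truth$y_true),
                       p_true = truth$p_true, y_true = truth$y_true),
            path, row.names = FALSE)
  invisible(path)
}

#' Posterior store on disk
#'
#' Writes a fitted model to a directory: `meta.json` (model type, sizes,
#' configuration echo), CSV matrices of the retained draws, and, when trees
#' were stored, one JSON ensemble per draw under `trees/`.  `read_posterior`
#' round-trips every stored numeric field.
#'
#' @param fit a `gtbart_fit` or `gtglm_fit`.
#' @param dir output directory (created).
#' @return `write_posterior()` returns `dir` invisibly; `read_posterior()`
#'   the reconstructed fit object.
#' @export
write_posterior <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "gtbart", version = as.character(packageVersion("gtbart")),
               model = fit$model, L = fit$L, n_keep = fit$n_keep,
               n_burn = fit$n_burn, thin = fit$thin, seed = fit$seed,
               K = fit$K, P = fit$P,
               known = fit$accuracy_prior$known,
               has_trees = length(fit$trees) > 0)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  mats <- c("se_draws", "sp_draws", "beta_draws", "split_counts",
            "eta_draws", "eta_test_draws")
  for (m in mats) {
    v <- fit[[m]]
    if (!is.null(v) && nrow(v) > 0)
      write.csv(as.data.frame(v), file.path(dir, paste0(m, ".csv")),
                row.names = FALSE)
  }
  vecs <- c("prob_train_mean", "prob_test_mean", "y_mean")
  for (m in vecs) {
    v <- fit[[m]]
    if (!is.null(v) && length(v) > 0)
      write.csv(data.frame(value = v), file.path(dir, paste0(m, ".csv")),
                row.names = FALSE)
  }
  if (length(fit$trees)) {
    tdir <- file.path(dir, "trees")
    dir.create(tdir, showWarnings = FALSE)
    for (s in seq_along(fit$trees))
      write_trees_json(fit$trees[[s]],
                       file.path(tdir, sprintf("draw_%05d.json", s)))
  }
  invisible(dir)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  out <- list(model = meta$model, L = meta$L, n_keep = meta$n_keep,
              n_burn = meta$n_burn, thin = meta$thin, K = meta$K,
              P = meta$P, seed = meta$seed,
              accuracy_prior = list(known = as.logical(meta$known)))
  read_mat <- function(name) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (file.exists(p)) as.matrix(read.csv(p)) else NULL
  }
  for (m in c("se_draws", "sp_draws", "beta_draws", "split_counts",
              "eta_draws", "eta_test_draws"))
    out[[m]] <- read_mat(m)
  for (m in c("prob_train_mean", "prob_test_mean", "y_mean")) {
    p <- file.path(dir, paste0(m, ".csv"))
    if (file.exists(p)) out[[m]] <- read.csv(p)$value
  }
  tdir <- file.path(dir, "trees")
  if (isTRUE(meta$has_trees) && dir.exists(tdir)) {
    files <- sort(list.files(tdir, full.names = TRUE))
    out$trees <- lapply(files, read_trees_json)
  }
  class(out) <- if (identical(meta$model, "glm")) "gtglm_fit" else "gtbart_fit"
  out
}
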