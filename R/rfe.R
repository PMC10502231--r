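#' Backward feature elimination with a random-forest regressor
#'
#' One seeded run of recursive (backward) feature elimination: starting
#' from all proteins, the cross-validated root-mean-square error (RMSE) of
#' a random-forest regression of the response on the current protein set is
#' estimated at each subset size of a descending schedule; after each size,
#' proteins are re-ranked by permutation importance on the full data and
#' the set is cut down to the next size. The run's selected set is the
#' importance-ranked protein list at the size with minimal estimated RMSE
#' (ties resolve to the smaller, more parsimonious size).
#'
#' Forests use 500 trees and `mtry = max(1, floor(p/3))` (the regression
#' default); all forest seeds derive deterministically from `seed`, so a
#' run is fully reproducible.
#'
#' @param pm A complete (preprocessed) [proteome_matrix]; see
#'   [preprocess_proteome()].
#' @param seed Integer seed for this run.
#' @param size_schedule Descending vector of subset sizes; default is the
#'   geometric schedule p, p/2, p/4, ... down to 8, then 8, 6, 4, 2,
#'   intersected with feasible sizes.
#' @param resampling RMSE estimator: `"loo"` (leave-one-out, default —
#'   stable at n = 12-14) or `"cv3"` (repeated 3-fold, 5 repeats).
#' @param num_trees Trees per forest (default 500).
#' @param importance `"permutation"` (default) or `"impurity"`.
#' @return An object of class `rfe_run`: `seed`, `selected` (protein ids,
#'   rank 1 first), `b` (selected set size), `rmse_profile` (tibble
#'   `size`, `rmse`), `best_rmse`, `best_size`.
#' @export
rfe_run <- function(pm, seed, size_schedule = NULL,
                    resampling = c("loo", "cv3"), num_trees = 500,
                    importance = c("permutation", "impurity")) {
  stopifnot(inherits(pm, "proteome_matrix"))
  resampling <- match.arg(resampling)
  importance <- match.arg(importance)
  x <- pm$intensities
  if (any(is.na(x)))
    stop("matrix contains missing values; run preprocess_proteome() first",
         call. = FALSE)
  y <- pm$response
  n <- ncol(x); p <- nrow(x)
  if (n < 6) stop("at least 6 samples are required", call. = FALSE)
  if (p < 2) stop("at least 2 proteins are required", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)

  sizes <- size_schedule %||% default_size_schedule(p)
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  if (any(sizes > p)) stop("size schedule exceeds protein count", call. = FALSE)
  if (any(sizes < 1)) stop("sizes must be positive", call. = FALSE)

  X <- t(x)  # samples x proteins for the learner

  withr::with_seed(seed, {
    current <- rownames(x)   # current feature set, importance-ordered later
    if (sizes[1] < p) {
      # schedule skips the full size: rank everything once before cutting
      imp0 <- .rf_importance(X[, sort(current), drop = FALSE], y, num_trees,
                             importance)
      current <- current[order(-imp0[current], current)]
    }
    profile <- numeric(length(sizes))
    rankings <- vector("list", length(sizes))

    for (i in seq_along(sizes)) {
      s <- sizes[i]
      feats <- current[seq_len(s)]
      # design columns in canonical (lexicographic) order so results do not
      # depend on the input matrix's row order
      Xs <- X[, sort(feats), drop = FALSE]
      profile[i] <- .rf_cv_rmse(Xs, y, resampling, num_trees)
      imp <- .rf_importance(Xs, y, num_trees, importance)
      ranked <- feats[order(-imp[feats], feats)]   # stable, deterministic
      rankings[[i]] <- ranked
      current <- ranked
    }

    # argmin RMSE; ties -> smallest size (sizes are descending, so the last
    # minimum encountered)
    best_i <- max(which(profile == min(profile)))
    structure(
      list(seed = seed,
           selected = rankings[[best_i]],
           b = sizes[best_i],
           rmse_profile = tibble::tibble(size = sizes, rmse = profile),
           best_rmse = profile[best_i],
           best_size = sizes[best_i]),
      class = "rfe_run")
  })
}

#' Default backward-elimination size schedule
#'
#' Descending geometric halving from `p` down to above 8, then the fixed
#' tail 8, 6, 4, 2, restricted to feasible sizes.
#'
#' @param p Number of proteins.
#' @return Descending integer vector of subset sizes.
#' @export
default_size_schedule <- function(p) {
  s <- as.integer(p)
  k <- floor(p / 2)
  while (k > 8) {
    s <- c(s, as.integer(k))
    k <- floor(k / 2)
  }
  tail_sizes <- c(8L, 6L, 4L, 2L)
  sort(unique(c(s, tail_sizes[tail_sizes <= p])), decreasing = TRUE)
}

# cross-validated RMSE of an RF regression on the given feature block
.rf_cv_rmse <- function(X, y, resampling, num_trees) {
  n <- nrow(X)
  folds <- if (resampling == "loo") {
    as.list(seq_len(n))
  } else {
    unlist(lapply(seq_len(5), function(r) {
      idx <- sample(rep_len(1:3, n))
      lapply(1:3, function(k) which(idx == k))
    }), recursive = FALSE)
  }
  sq_err <- unlist(lapply(folds, function(test) {
    fit <- .rf_fit(X[-test, , drop = FALSE], y[-test], num_trees,
                   importance = "none")
    pred <- stats::predict(fit, data = X[test, , drop = FALSE],
                           num.threads = 1)$predictions
    (pred - y[test])^2
  }))
  sqrt(mean(sq_err))
}

.rf_importance <- function(X, y, num_trees, importance) {
  fit <- .rf_fit(X, y, num_trees, importance = importance)
  imp <- fit$variable.importance[colnames(X)]
  imp[is.na(imp)] <- 0
  names(imp) <- colnames(X)
  imp
}

.rf_fit <- function(X, y, num_trees, importance) {
  ranger::ranger(
    x = X, y = y,
    num.trees = num_trees,
    mtry = max(1L, floor(ncol(X) / 3)),
    importance = importance,
    seed = sample.int(.Machine$integer.max, 1),
    num.threads = 1
  )
}

#' @export
print.rfe_run <- function(x, ...) {
  cat(sprintf("<rfe_run> seed %d: %d proteins selected (RMSE %.4f)\n",
              x$seed, x$b, x$best_rmse))
  invisible(x)
}

#' Seeded ensemble of backward-elimination runs
#'
#' Runs [rfe_run()] `n_runs` times with seeds `base_seed + 1, ...,
#' base_seed + n_runs`, exploiting the stochasticity of random forests to
#' obtain an ensemble of per-run optimal protein sets that are integrated
#' by [consensus_scores()]. Typical ensemble sizes are 30 runs (the more
#' heterogeneous BxPC3-like setting) and 10 runs (Panc-1-like).
#'
#' @param pm A complete [proteome_matrix].
#' @param n_runs Number of runs (>= 1; default 30).
#' @param base_seed Base seed; run k uses `base_seed + k`.
#' @param ... Passed on to [rfe_run()].
#' @return An object of class `rfe_ensemble`: a list of `rfe_run` results
#'   with attributes `n_runs` and `base_seed`.
#' @export
run_ensemble <- function(pm, n_runs = 30L, base_seed = 1L, ...) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  runs <- purrr::map(seq_len(n_runs),
                     function(k) rfe_run(pm, seed = base_seed + k, ...))
  structure(runs, class = "rfe_ensemble",
            n_runs = as.integer(n_runs), base_seed = as.integer(base_seed))
}

#' @export
print.rfe_ensemble <- function(x, ...) {
  cat("<rfe_ensemble>", length(x), "runs, base seed",
      attr(x, "base_seed"), "\n")
  cat("  selected set sizes:",
      paste(purrr::map_int(x, "b"), collapse = " "), "\n")
  invisible(x)
}
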