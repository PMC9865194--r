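#' Hyperparameters for the gradient-boosted ranker
#'
#' The tunable grid mirrors the published configuration space: learning rate
#' in \{0.05, 0.1, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0\} (default 0.5), 20
#' boosting rounds, gamma (minimum split loss) in \{0, 0.5, 1, 2\} (default
#' 0), and max tree depth in \{1, 3, 6, 8\} (default 6). Screening uses
#' `cv_folds`-fold cross-validation (default 10). Values off the grids are
#' rejected unless `allow_any = TRUE`.
#'
#' @param learning_rate shrinkage applied to each tree's leaf weights.
#' @param n_estimators number of boosting rounds.
#' @param gamma minimum loss reduction required to make a split.
#' @param max_depth maximum tree depth.
#' @param cv_folds folds used in the importance-screening stage.
#' @param seed integer seed controlling fold assignment.
#' @param reg_lambda L2 penalty on leaf weights (library default 1; not part
#'   of the published grid).
#' @param log1p_target fit `log1p(counts)` instead of raw counts.
#' @param eliminate_with_cv if `TRUE`, each backward-elimination step
#'   averages importances over CV folds instead of one full-data fit.
#' @param allow_any skip grid validation.
#' @return an object of class `boost_params`.
#' @export
boost_params <- function(learning_rate = 0.5, n_estimators = 20, gamma = 0,
                         max_depth = 6, cv_folds = 10, seed = 1,
                         reg_lambda = 1, log1p_target = FALSE,
                         eliminate_with_cv = FALSE, allow_any = FALSE) {
  if (!allow_any) {
    check_grid(learning_rate, c(0.05, 0.1, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0),
               "learning_rate")
    check_grid(gamma, c(0, 0.5, 1, 2), "gamma")
    check_grid(max_depth, c(1, 3, 6, 8), "max_depth")
  }
  stopifnot(n_estimators >= 1, cv_folds >= 2, reg_lambda >= 0)
  structure(list(learning_rate = learning_rate,
                 n_estimators = as.integer(n_estimators),
                 gamma = gamma, max_depth = as.integer(max_depth),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 reg_lambda = reg_lambda, log1p_target = isTRUE(log1p_target),
                 eliminate_with_cv = isTRUE(eliminate_with_cv)),
            class = "boost_params")
}

check_grid <- function(value, grid, name) {
  if (!any(abs(value - grid) < 1e-12)) {
    stop(sprintf("%s = %s is not in the allowed grid {%s}; set allow_any = TRUE to override",
                 name, format(value), paste(grid, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Hyperparameters for the random-forest baseline ranker
#'
#' Defaults follow the published setup (1000 trees) with classical
#' regression-forest conventions for everything unspecified there:
#' `mtry = max(floor(p/3), 1)` features tried per split (set `NULL` to use
#' that rule) and terminal node size 5.
#'
#' @param n_trees number of trees per forest.
#' @param mtry features tried per split; `NULL` for `max(floor(p/3), 1)`.
#' @param min_node minimum terminal node size.
#' @param seed integer seed; the forest is bit-reproducible per seed.
#' @param screen_top_k screen to this many features by permutation
#'   importance before backward elimination; `Inf` eliminates from the full
#'   feature set.
#' @return an object of class `forest_params`.
#' @export
forest_params <- function(n_trees = 1000, mtry = NULL, min_node = 5,
                          seed = 1, screen_top_k = 20) {
  stopifnot(n_trees >= 1, min_node >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 min_node = as.integer(min_node), seed = as.integer(seed),
                 screen_top_k = screen_top_k),
            class = "forest_params")
}

#' @export
print.boost_params <- function(x, ...) {
  cat("boost_params: eta =", x$learning_rate, "rounds =", x$n_estimators,
      "gamma =", x$gamma, "depth =", x$max_depth,
      "cv =", x$cv_folds, "seed =", x$seed, "\n")
  invisible(x)
}

#' @export
print.forest_params <- function(x, ...) {
  cat("forest_params: trees =", x$n_trees,
      "mtry =", if (is.null(x$mtry)) "p/3" else x$mtry,
      "min_node =", x$min_node, "seed =", x$seed, "\n")
  invisible(x)
}
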