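#' Random-forest baseline ranker
#'
#' The comparison algorithm: a regression random forest predicts regional
#' mutation density from the chromatin features; importance of feature m is
#' the classical out-of-bag permutation score (mean over trees of the OOB
#' MSE increase after permuting column m within the tree's OOB rows);
#' ranking proceeds by the same greedy backward elimination as the boosted
#' ranker.
#'
#' @name rf_baseline
NULL

#' Out-of-bag permutation importance from a regression forest
#'
#' @inheritParams screen_importance
#' @param params a [forest_params()] object.
#' @return a `permutation_importance`: list with `scores` (named; positive
#'   = informative, may be negative for irrelevant features), `oob_mse`,
#'   `trees_used`, and `metric`.
#' @export
rf_importance <- function(y, X, params = forest_params()) {
  yv <- check_alignment(y, X)
  if (ncol(X) < 2) stop("need at least 2 features")
  mtry <- params$mtry %||% max(floor(ncol(X) / 3), 1)
  fit <- .rf_fit_cpp(unclass(X), yv, params$n_trees, mtry, params$min_node,
                     seed_derive(params$seed, 23L))
  if (fit$trees_skipped > 0)
    warning(sprintf("%d tree(s) had no out-of-bag rows and were skipped for importance",
                    fit$trees_skipped))
  structure(list(scores = stats::setNames(fit$importance, colnames(X)),
                 oob_mse = fit$oob_mse, trees_used = fit$trees_used,
                 metric = "oob_permutation_mse_increase"),
            class = "permutation_importance")
}

# importance for any feature count, handling the p == 1 boundary the
# elimination loop can reach
rf_importance_any <- function(yv, X, params, seed_tag) {
  p <- params
  p$seed <- seed_tag
  if (ncol(X) >= 2) return(rf_importance(yv, X, p)$scores)
  mtry <- params$mtry %||% 1
  fit <- .rf_fit_cpp(unclass(X), yv, params$n_trees, max(mtry, 1),
                     params$min_node, seed_derive(seed_tag, 23L))
  stats::setNames(fit$importance, colnames(X))
}

#' Backward elimination with the random-forest ranker
#'
#' Screens to the `top_k` features by permutation importance, then
#' iteratively refits the forest and removes the least important feature
#' (ties by ascending feature id) until one survives. Set
#' `params$screen_top_k = Inf` to eliminate from the full feature set.
#'
#' @inheritParams rf_importance
#' @param top_k screened subset size (default from `params$screen_top_k`).
#' @return a `ranking_result` with `algorithm = "random_forest"`.
#' @export
rf_backward_eliminate <- function(y, X, params = forest_params(),
                                  top_k = params$screen_top_k) {
  yv <- check_alignment(y, X)
  if (ncol(X) < 1) stop("empty feature set")
  k <- min(top_k, ncol(X))
  if (ncol(X) >= 2 && k < ncol(X)) {
    sc <- rf_importance(yv, X, params)
    keep <- names(sort_by_importance(sc$scores))[seq_len(k)]
  } else {
    sc <- NULL
    keep <- colnames(X)
  }
  current <- sort(keep)
  eliminated <- character(0)
  step <- 0L
  while (length(current) > 1) {
    step <- step + 1L
    imp <- rf_importance_any(yv, X[, current, drop = FALSE], params,
                             seed_derive(params$seed, 31L, step))
    drop_id <- argmin_feature(imp)
    eliminated <- c(eliminated, drop_id)
    current <- setdiff(current, drop_id)
  }
  structure(list(ranked_features = c(current, rev(eliminated)),
                 elimination_order = c(eliminated, current),
                 params = params,
                 screen_importances = sc,
                 algorithm = "random_forest"),
            class = "ranking_result")
}

#' Repeated random-forest origin predictions
#'
#' As [repeat_predictions()] but with the forest ranker; each repeat uses
#' seed `base_seed + i - 1`.
#'
#' @inheritParams repeat_predictions
#' @param params a [forest_params()] object.
#' @return a `reproducibility_report` with `algorithm = "random_forest"`.
#' @export
rf_repeat_predictions <- function(y, X, meta, params = forest_params(),
                                  n_repeats = 20, base_seed = 1,
                                  expected_type = NULL, sample_id = "sample") {
  stopifnot(n_repeats >= 1)
  runs <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    p_i <- params
    p_i$seed <- as.integer(base_seed + i - 1)
    r <- rf_backward_eliminate(y, X, p_i)
    pred <- assign_origin(r, meta, sample_id, expected_type)
    runs[[i]] <- data.frame(seed = p_i$seed, rank1_feature = pred$rank1_feature,
                            predicted_type = pred$predicted_type,
                            match = isTRUE(pred$match),
                            stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, runs)
  acc <- mean(runs$match)
  structure(list(sample_id = sample_id, n_repeats = n_repeats,
                 accuracy = acc, reproducible = acc %in% c(0, 1),
                 expected_type = expected_type, runs = runs,
                 algorithm = "random_forest"),
            class = "reproducibility_report")
}
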