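#' Gradient-boosted screening, backward elimination and origin assignment
#'
#' The ranker regresses per-window mutation counts on the chromatin-mark
#' feature matrix with a depth-limited, shrinkage-regularised boosted-tree
#' model (squared-error objective), screens features by cross-validated
#' total-gain importance, then greedily eliminates the least important
#' feature one refit at a time until a single feature survives. The
#' survivor ("rank 1") names the chromatin landscape most similar to the
#' sample's regional mutation density; its tissue or cell type is the
#' predicted tissue/cell-of-origin.
#'
#' @name ranking_core
NULL

as_counts <- function(y) {
  if (inherits(y, "mutation_profile")) y$counts else as.numeric(y)
}

check_alignment <- function(y, X) {
  if (inherits(y, "mutation_profile") && !is.null(attr(X, "window_ref"))) {
    if (!is.na(y$window_ref) && y$window_ref != attr(X, "window_ref"))
      stop("mutation profile and chromatin matrix use different window sets")
  }
  yv <- as_counts(y)
  if (length(yv) != nrow(X))
    stop(sprintf("profile has %d windows but matrix has %d rows",
                 length(yv), nrow(X)))
  if (any(!is.finite(yv)) || any(!is.finite(X)))
    stop("non-finite values in inputs")
  yv
}

# one boosted fit; deterministic given (X, y, params)
fit_booster <- function(X, y, params) {
  if (params$log1p_target) y <- log1p(y)
  fit <- .gbt_fit_cpp(unclass(X), y,
                      params$learning_rate, params$n_estimators,
                      params$max_depth, params$gamma, params$reg_lambda,
                      1.0, mean(y))
  names(fit$importance) <- colnames(X)
  fit
}

cv_fold_assign <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Screen features by cross-validated gain importance
#'
#' Fits the boosted regressor on the training split of each of
#' `params$cv_folds` folds and averages each feature's total-gain
#' importance across folds. Features the trees never split on score 0.
#'
#' @param y a `mutation_profile` or numeric count vector (one value per
#'   window).
#' @param X a `chromatin_matrix` (windows x features).
#' @param params a [boost_params()] object; `params$seed` fixes the fold
#'   assignment and hence the result.
#' @return an `importance_vector`: list with `scores` (named, one per
#'   feature) and `metric` (`"total_gain_cv_mean"`).
#' @export
screen_importance <- function(y, X, params = boost_params()) {
  yv <- check_alignment(y, X)
  if (ncol(X) < 2) stop("need at least 2 features to screen")
  if (nrow(X) < params$cv_folds)
    stop("fewer rows than cv_folds")
  folds <- cv_fold_assign(nrow(X), params$cv_folds, seed_derive(params$seed, 11L))
  acc <- numeric(ncol(X))
  for (f in seq_len(params$cv_folds)) {
    train <- folds != f
    fit <- fit_booster(X[train, , drop = FALSE], yv[train], params)
    acc <- acc + fit$importance
  }
  structure(list(scores = stats::setNames(acc / params$cv_folds, colnames(X)),
                 metric = "total_gain_cv_mean"),
            class = "importance_vector")
}

# least-important feature under the deterministic tie rule:
# smallest importance, ties broken by ascending feature id
argmin_feature <- function(imp) {
  ids <- names(imp)
  cand <- ids[imp <= min(imp) + 0]
  sort(cand)[1]
}

#' Greedy backward elimination over a screened feature subset
#'
#' Repeatedly fits the boosted regressor on the surviving features (full
#' data, fixed hyperparameters) and removes the feature with the smallest
#' total-gain importance — ties, including never-used features at
#' importance 0, broken by ascending feature id — until one feature
#' remains. Rank 1 is the survivor.
#'
#' @inheritParams screen_importance
#' @param X_sub the matrix restricted to the screened features.
#' @return a `ranking_result`: `ranked_features` (rank 1 first),
#'   `elimination_order` (first-eliminated first), `params`, `algorithm`.
#' @export
backward_eliminate <- function(y, X_sub, params = boost_params()) {
  yv <- check_alignment(y, X_sub)
  if (ncol(X_sub) < 1) stop("empty feature set")
  current <- colnames(X_sub)
  eliminated <- character(0)
  while (length(current) > 1) {
    Xc <- X_sub[, current, drop = FALSE]
    imp <- if (params$eliminate_with_cv) {
      screen_importance(yv, Xc, params)$scores
    } else {
      fit_booster(Xc, yv, params)$importance
    }
    drop_id <- argmin_feature(imp)
    eliminated <- c(eliminated, drop_id)
    current <- setdiff(current, drop_id)
  }
  structure(list(ranked_features = c(current, rev(eliminated)),
                 elimination_order = c(eliminated, current),
                 params = params, screen_importances = NULL,
                 algorithm = "boost"),
            class = "ranking_result")
}

#' Rank chromatin features against a mutation profile
#'
#' The full two-stage procedure: cross-validated importance screening to
#' the top `min(20, n_features)` features (ties by ascending feature id),
#' then backward elimination on that subset.
#'
#' @inheritParams screen_importance
#' @param top_k screened subset size (default 20).
#' @return a `ranking_result` with `screen_importances` attached.
#' @export
rank_features <- function(y, X, params = boost_params(), top_k = 20) {
  yv <- check_alignment(y, X)
  k <- min(top_k, ncol(X))
  if (ncol(X) >= 2) {
    sc <- screen_importance(yv, X, params)
    keep <- names(sort_by_importance(sc$scores))[seq_len(k)]
  } else {
    sc <- structure(list(scores = stats::setNames(rep(NA_real_, ncol(X)),
                                                  colnames(X)),
                         metric = "single_feature"),
                    class = "importance_vector")
    keep <- colnames(X)
  }
  res <- backward_eliminate(yv, X[, keep, drop = FALSE], params)
  res$screen_importances <- sc
  res
}

# descending score, ties ascending id
sort_by_importance <- function(scores) {
  scores[order(-scores, names(scores))]
}

#' Assign a tissue/cell-of-origin from a ranking
#'
#' Looks up the rank-1 feature's tissue or cell type in the feature
#' metadata; that type is the predicted origin.
#'
#' @param r a `ranking_result`.
#' @param meta feature metadata (feature_id, tissue_type, mark, source).
#' @param sample_id label for the prediction.
#' @param expected_type optional known origin; when given, `match` reports
#'   whether the prediction agrees.
#' @return an `origin_prediction`: `sample_id`, `predicted_type`,
#'   `rank1_feature`, `top20`, `expected_type`, `match`, `algorithm`.
#' @export
assign_origin <- function(r, meta, sample_id = "sample", expected_type = NULL) {
  stopifnot(inherits(r, "ranking_result"))
  meta <- validate_metadata(meta)
  rank1 <- r$ranked_features[1]
  row <- match(rank1, meta$feature_id)
  if (is.na(row)) stop("rank-1 feature missing from metadata: ", rank1)
  predicted <- meta$tissue_type[row]
  structure(list(sample_id = sample_id, predicted_type = predicted,
                 rank1_feature = rank1, top20 = r$ranked_features,
                 expected_type = expected_type,
                 match = if (is.null(expected_type)) NULL
                         else identical(predicted, expected_type),
                 algorithm = r$algorithm),
            class = "origin_prediction")
}

#' Repeat the ranking under fresh seeds and report reproducibility
#'
#' Runs the full ranking with seeds `base_seed .. base_seed + n_repeats - 1`
#' and reports the fraction of runs whose predicted origin matches
#' `expected_type`. A sample is called reproducible when that accuracy is
#' exactly 0 or exactly 1 (every run agrees).
#'
#' @inheritParams rank_features
#' @param meta feature metadata.
#' @param n_repeats number of repeated runs.
#' @param base_seed first seed.
#' @param expected_type the origin to score against.
#' @return a `reproducibility_report`: `accuracy`, `reproducible`, and a
#'   per-run data.frame `runs` (seed, rank1_feature, predicted_type, match).
#' @export
repeat_predictions <- function(y, X, meta, params = boost_params(),
                               n_repeats = 100, base_seed = 1,
                               expected_type = NULL, sample_id = "sample") {
  stopifnot(n_repeats >= 1)
  runs <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    p_i <- params
    p_i$seed <- as.integer(base_seed + i - 1)
    r <- rank_features(y, X, p_i)
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
                 algorithm = "boost"),
            class = "reproducibility_report")
}

#' Out-of-fold variance explained by the boosted model
#'
#' Pooled out-of-fold R-squared: each fold is predicted by a model trained
#' on the other folds, and `1 - SSE/SST` is computed over the pooled
#' predictions against the global mean.
#'
#' @inheritParams screen_importance
#' @param X_sub feature matrix (any number of columns >= 1).
#' @return a single number (can be negative for uninformative features).
#' @export
cv_variance_explained <- function(y, X_sub, params = boost_params()) {
  yv <- check_alignment(y, X_sub)
  if (stats::var(yv) == 0) stop("target has zero variance")
  if (nrow(X_sub) < params$cv_folds) stop("fewer rows than cv_folds")
  folds <- cv_fold_assign(nrow(X_sub), params$cv_folds,
                          seed_derive(params$seed, 11L))
  pred <- numeric(length(yv))
  for (f in seq_len(params$cv_folds)) {
    train <- folds != f
    fit <- fit_booster(X_sub[train, , drop = FALSE], yv[train], params)
    p <- .gbt_predict_cpp(fit, unclass(X_sub[!train, , drop = FALSE]))
    pred[!train] <- if (params$log1p_target) expm1(p) else p
  }
  1 - sum((yv - pred)^2) / sum((yv - mean(yv))^2)
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("ranking_result (%s): rank 1 = %s; %d features ranked\n",
              x$algorithm, x$ranked_features[1], length(x$ranked_features)))
  invisible(x)
}

#' @export
print.origin_prediction <- function(x, ...) {
  cat(sprintf("origin_prediction '%s': %s (rank-1 feature %s)%s\n",
              x$sample_id, x$predicted_type, x$rank1_feature,
              if (!is.null(x$match))
                sprintf(" [expected %s: %s]", x$expected_type,
                        if (x$match) "match" else "mismatch") else ""))
  invisible(x)
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf("reproducibility_report '%s': accuracy %.3f over %d runs (%s)\n",
              x$sample_id, x$accuracy, x$n_repeats,
              if (x$reproducible) "reproducible" else "not reproducible"))
  invisible(x)
}

#' Write a ranking result with its origin call to TSV and JSON
#'
#' The TSV lists rank, feature id, tissue type, mark and screening
#' importance; the JSON carries the same table plus the hyperparameters and
#' seed for provenance.
#'
#' @param r a `ranking_result`.
#' @param meta feature metadata.
#' @param path_prefix output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the two paths, invisibly.
#' @export
write_ranking <- function(r, meta, path_prefix) {
  meta <- validate_metadata(meta)
  idx <- match(r$ranked_features, meta$feature_id)
  sc <- r$screen_importances$scores
  df <- data.frame(rank = seq_along(r$ranked_features),
                   feature_id = r$ranked_features,
                   tissue_type = meta$tissue_type[idx],
                   mark = meta$mark[idx],
                   screen_importance =
                     if (is.null(sc)) NA_real_ else unname(sc[r$ranked_features]),
                   stringsAsFactors = FALSE)
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(algorithm = r$algorithm,
                            params = unclass(r$params),
                            ranking = df),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, json))
}
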