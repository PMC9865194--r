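test_that("screening importance finds an exactly encoded driver column", {
  pl <- planted_xy(n = 500, p_noise = 30, seed = 1, exact = TRUE)
  params <- boost_params(seed = 1)
  sc <- screen_importance(pl$y, pl$X, params)
  expect_named(sc$scores, colnames(pl$X))
  expect_equal(names(which.max(sc$scores)), pl$driver)
  expect_equal(sc$metric, "total_gain_cv_mean")
  # the boosted fit itself must essentially memorise y = x_driver
  fit <- epiorigin:::fit_booster(pl$X, pl$y, params)
  r2 <- 1 - sum((pl$y - fit$train_pred)^2) / sum((pl$y - mean(pl$y))^2)
  expect_gt(r2, 0.9)
})

test_that("a constant target yields zero importance everywhere", {
  pl <- planted_xy(n = 120, p_noise = 5, seed = 2)
  sc <- screen_importance(rep(3, 120), pl$X, boost_params(seed = 1))
  expect_true(all(sc$scores == 0))
})

test_that("screening is deterministic per seed and validates its inputs", {
  pl <- planted_xy(n = 200, p_noise = 5, seed = 3, exact = FALSE)
  s1 <- screen_importance(pl$y, pl$X, boost_params(seed = 9))
  s2 <- screen_importance(pl$y, pl$X, boost_params(seed = 9))
  expect_identical(s1, s2)

  expect_error(screen_importance(pl$y, pl$X[, 1, drop = FALSE],
                                 boost_params()), "2 features")
  expect_error(screen_importance(c(pl$y[-1], NA), pl$X, boost_params()),
               "non-finite")
  expect_error(screen_importance(pl$y[1:5], pl$X[1:5, ],
                                 boost_params(cv_folds = 10)), "cv_folds")
})

test_that("backward elimination ranks an exact driver first and handles edge cases", {
  # single feature: identity
  pl <- planted_xy(n = 100, p_noise = 1, seed = 4)
  r1 <- backward_eliminate(pl$y, pl$X[, "driver", drop = FALSE], boost_params())
  expect_equal(r1$ranked_features, "driver")
  expect_equal(r1$elimination_order, "driver")

  # two features, y identical to one of them
  X2 <- pl$X[, c("driver", "noise01")]
  r2 <- backward_eliminate(pl$y, X2, boost_params())
  expect_equal(r2$ranked_features[1], "driver")
  expect_equal(r2$elimination_order, c("noise01", "driver"))

  expect_error(backward_eliminate(pl$y, pl$X[, integer(0)], boost_params()),
               "empty")
})

test_that("each elimination step removes the argmin of a re-extracted importance", {
  pl <- planted_xy(n = 300, p_noise = 4, seed = 5, exact = FALSE, b = 1)
  params <- boost_params(seed = 7)
  r <- backward_eliminate(pl$y, pl$X, params)
  # oracle: replay the loop with independent full-data fits
  current <- colnames(pl$X)
  for (step in seq_len(ncol(pl$X) - 1)) {
    imp <- epiorigin:::fit_booster(pl$X[, current, drop = FALSE], pl$y,
                                   params)$importance
    ids <- names(imp)[imp == min(imp)]
    expected_drop <- sort(ids)[1]
    expect_equal(r$elimination_order[step], expected_drop)
    current <- setdiff(current, expected_drop)
  }
  expect_equal(r$ranked_features, rev(r$elimination_order))
})

test_that("rank_features screens to min(20, p) and recovers a planted driver", {
  pl <- planted_xy(n = 500, p_noise = 24, seed = 6, exact = TRUE)
  r <- rank_features(pl$y, pl$X, boost_params(seed = 1))
  expect_length(r$ranked_features, 20)
  expect_equal(r$ranked_features[1], pl$driver)
  expect_setequal(r$ranked_features,
                  names(sort_by_imp <- sort(r$screen_importances$scores,
                                            decreasing = TRUE))[1:20])

  # small-p path: screening cannot drop anything
  r3 <- rank_features(pl$y, pl$X[, 1:3], boost_params(seed = 1))
  expect_length(r3$ranked_features, 3)
  expect_setequal(r3$ranked_features, colnames(pl$X)[1:3])

  # different seeds may reorder, but output stays a permutation of a top-20 set
  r_b <- rank_features(pl$y, pl$X, boost_params(seed = 2))
  expect_length(r_b$ranked_features, 20)
  expect_setequal(r_b$ranked_features,
                  names(sort(r_b$screen_importances$scores,
                             decreasing = TRUE))[1:20])
})

test_that("origin assignment looks the rank-1 feature up in the metadata", {
  meta <- data.frame(feature_id = c("liver_H3K4me1", "colon_H3K4me1"),
                     tissue_type = c("liver", "colon"),
                     mark = "H3K4me1", source = "test")
  r <- structure(list(ranked_features = c("liver_H3K4me1", "colon_H3K4me1"),
                      elimination_order = c("colon_H3K4me1", "liver_H3K4me1"),
                      params = boost_params(), screen_importances = NULL,
                      algorithm = "boost"),
                 class = "ranking_result")
  p <- assign_origin(r, meta, "s1")
  expect_equal(p$predicted_type, "liver")
  expect_null(p$match)
  expect_true(assign_origin(r, meta, "s1", "liver")$match)
  expect_false(assign_origin(r, meta, "s1", "colon")$match)
  r$ranked_features[1] <- "unknown_feat"
  expect_error(assign_origin(r, meta), "missing from metadata")
})

test_that("repeated runs on a deterministic planted signal are fully reproducible", {
  w <- small_world(n = 300, seed = 10, b = 2)
  rep <- repeat_predictions(w$y, w$X, w$meta, boost_params(),
                            n_repeats = 5, base_seed = 1,
                            expected_type = w$driver)
  expect_equal(rep$accuracy, 1.0)
  expect_true(rep$reproducible)
  expect_equal(nrow(rep$runs), 5)
  expect_equal(rep$runs$seed, 1:5)

  # expected label that no feature carries: accuracy exactly 0
  rep0 <- repeat_predictions(w$y, w$X, w$meta, boost_params(),
                             n_repeats = 2, base_seed = 1,
                             expected_type = "kidney")
  expect_equal(rep0$accuracy, 0.0)
  expect_true(rep0$reproducible)

  rep1 <- repeat_predictions(w$y, w$X, w$meta, boost_params(),
                             n_repeats = 1, base_seed = 3,
                             expected_type = w$driver)
  expect_true(rep1$accuracy %in% c(0, 1))
})

test_that("out-of-fold variance explained separates signal from noise", {
  pl <- planted_xy(n = 500, p_noise = 0, seed = 11, exact = TRUE)
  Xd <- pl$X[, "driver", drop = FALSE]
  r2 <- cv_variance_explained(pl$y, Xd, boost_params(seed = 1))
  expect_gt(r2, 0.9)

  # location invariance: shifting y leaves the tree structure and R^2 alone
  r2_shift <- cv_variance_explained(pl$y + 100, Xd, boost_params(seed = 1))
  expect_equal(r2_shift, r2, tolerance = 1e-8)

  # independent noise target: near-zero R^2 in expectation
  r2_noise <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      Xn <- matrix(rnorm(2000 * 5), 2000, 5)
      colnames(Xn) <- paste0("f", 1:5)
      yn <- rnorm(2000)
      cv_variance_explained(yn, Xn, boost_params(seed = s))
    })
  }, 0)
  expect_lte(mean(r2_noise), 0.1)

  expect_error(cv_variance_explained(rep(1, 500), Xd, boost_params()),
               "zero variance")
})
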