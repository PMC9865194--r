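#' Region-subset robustness analyses
#'
#' Tools to test whether an origin call is stable when the ranker sees only
#' a subset of the genomic windows: random subsets of fixed size, and
#' subsets constrained to contain a given proportion of enhancer-containing
#' windows.
#'
#' @name subset_analysis
NULL

#' Flag windows containing enhancer intervals
#'
#' A window is flagged when at least one enhancer interval overlaps it by
#' one or more base pairs (an enhancer spanning a boundary flags both
#' windows).
#'
#' @param ws a `window_set`.
#' @param enhancers data.frame with chrom/start/end columns or a BED3 path
#'   (0-based half-open).
#' @return logical vector, one flag per retained window.
#' @export
mark_enhancer_windows <- function(ws, enhancers) {
  stopifnot(inherits(ws, "window_set"))
  iv <- read_intervals(enhancers)
  if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, n_windows(ws)))
  win_gr <- GenomicRanges::GRanges(ws$windows$chrom,
                                   IRanges::IRanges(ws$windows$start + 1,
                                                    ws$windows$end))
  enh_gr <- GenomicRanges::GRanges(iv$chrom,
                                   IRanges::IRanges(iv$start + 1, iv$end))
  IRanges::overlapsAny(win_gr, enh_gr)
}

#' Sample a window subset at a fixed enhancer proportion
#'
#' Draws `round(proportion * n_total)` indices (half-up rounding) without
#' replacement from the masked (enhancer-containing) windows — all of them
#' if fewer exist, with the shortfall filled from unmasked windows — then
#' fills up to `n_total` from the unmasked windows. With `proportion =
#' NULL` the draw is simple random over all windows.
#'
#' @param ws a `window_set`.
#' @param mask logical vector over windows (required with `proportion`).
#' @param n_total subset size.
#' @param proportion target fraction of masked windows in the subset, or
#'   `NULL`.
#' @param seed integer seed; the draw is deterministic per seed.
#' @return integer vector of `n_total` distinct window indices (0-based,
#'   matching the `index` column), sorted.
#' @export
sample_subset <- function(ws, mask = NULL, n_total, proportion = NULL, seed = 1) {
  N <- n_windows(ws)
  if (n_total > N) stop(sprintf("n_total (%d) exceeds window count (%d)",
                                n_total, N))
  stopifnot(n_total >= 1)
  if (!is.null(proportion)) {
    if (is.null(mask)) stop("proportion requires an enhancer mask")
    stopifnot(length(mask) == N, proportion >= 0, proportion <= 1)
  }
  all_idx <- seq_len(N)
  with_seed(seed, {
    if (is.null(proportion)) {
      picked <- sample(all_idx, n_total)
    } else {
      masked <- all_idx[mask]
      unmasked <- all_idx[!mask]
      want_masked <- floor(proportion * n_total + 0.5) # round half-up
      take_masked <- min(want_masked, length(masked))
      pick_m <- if (take_masked > 0) sample_exact(masked, take_masked) else integer(0)
      need <- n_total - take_masked
      take_un <- min(need, length(unmasked))
      pick_u <- if (take_un > 0) sample_exact(unmasked, take_un) else integer(0)
      picked <- c(pick_m, pick_u)
      if (length(picked) < n_total) {
        # unmasked pool exhausted: top up from remaining masked windows
        rest <- setdiff(masked, pick_m)
        picked <- c(picked, sample_exact(rest, n_total - length(picked)))
      }
    }
    sort(ws$windows$index[picked])
  })
}

# sample() without the length-1 surprise
sample_exact <- function(x, k) {
  if (length(x) == 1) return(if (k >= 1) x else integer(0))
  sample(x, k)
}

#' Subset-accuracy of the origin call
#'
#' Computes the reference origin prediction on all windows, then for each
#' iteration draws a window subset, restricts the profile and matrix to it,
#' reruns the chosen ranker (same hyperparameters and ranker seed as the
#' reference — randomness across iterations comes only from the subset
#' draw), and scores agreement with the reference prediction.
#'
#' @inheritParams rank_features
#' @param meta feature metadata.
#' @param n_regions subset size.
#' @param n_iterations number of random subsets.
#' @param mask optional enhancer flags (see [mark_enhancer_windows()]).
#' @param proportion optional enhancer proportion for the draws.
#' @param seed top-level seed; per-iteration draw seeds are derived as
#'   `seed_derive(seed, n_regions, iteration)` so results for one size
#'   never depend on which other sizes are run.
#' @param algorithm `"boost"` or `"forest"`.
#' @param forest_params_obj parameters when `algorithm = "forest"`.
#' @param reference precomputed full-window reference prediction (a tissue
#'   label); computed when `NULL`. [sweep_subsets()] uses this to compute
#'   the reference once per sweep.
#' @return a `subset_accuracy_result`: reference prediction, per-iteration
#'   predictions, and `accuracy` (fraction matching the reference).
#' @export
subset_accuracy <- function(y, X, meta, params = boost_params(),
                            n_regions, n_iterations = 100,
                            mask = NULL, proportion = NULL, seed = 1,
                            algorithm = c("boost", "forest"),
                            forest_params_obj = forest_params(),
                            reference = NULL) {
  algorithm <- match.arg(algorithm)
  yv <- check_alignment(y, X)
  ws_like <- list(windows = data.frame(index = seq_along(yv) - 1L))
  run_ranker <- function(rows) {
    ys <- yv[rows]
    Xs <- unclass(X)[rows, , drop = FALSE]
    r <- if (algorithm == "boost") rank_features(ys, Xs, params)
         else rf_backward_eliminate(ys, Xs, forest_params_obj)
    assign_origin(r, meta)$predicted_type
  }
  if (is.null(reference)) reference <- run_ranker(seq_along(yv))
  preds <- character(n_iterations)
  for (it in seq_len(n_iterations)) {
    draw_seed <- seed_derive(seed, n_regions, it)
    idx0 <- sample_subset(structure(ws_like, class = "window_set"),
                          mask = mask, n_total = n_regions,
                          proportion = proportion, seed = draw_seed)
    preds[it] <- run_ranker(idx0 + 1L)
  }
  structure(list(n_regions = n_regions, proportion = proportion,
                 n_iterations = n_iterations, seed = seed,
                 algorithm = algorithm,
                 reference_prediction = reference,
                 predictions = preds,
                 accuracy = mean(preds == reference)),
            class = "subset_accuracy_result")
}

#' Sweep subset sizes and report accuracy per size
#'
#' One [subset_accuracy()] per size; seeds derive from the top-level seed
#' and the size, so adding sizes never perturbs existing results.
#'
#' @inheritParams subset_accuracy
#' @param sizes ascending vector of subset sizes.
#' @return list of `subset_accuracy_result`, plus a `summary` data.frame
#'   attribute (size, accuracy).
#' @export
sweep_subsets <- function(y, X, meta, params = boost_params(),
                          sizes, n_iterations = 100, seed = 1,
                          algorithm = "boost",
                          forest_params_obj = forest_params()) {
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be ascending")
  # the full-window reference is the same for every size: compute it once
  ref <- subset_accuracy(y, X, meta, params, n_regions = length(as_counts(y)),
                         n_iterations = 0, seed = seed, algorithm = algorithm,
                         forest_params_obj = forest_params_obj)$reference_prediction
  out <- lapply(sizes, function(s) {
    subset_accuracy(y, X, meta, params, n_regions = s,
                    n_iterations = n_iterations, seed = seed,
                    algorithm = algorithm,
                    forest_params_obj = forest_params_obj,
                    reference = ref)
  })
  attr(out, "summary") <- data.frame(
    size = sizes, accuracy = vapply(out, function(r) r$accuracy, 0))
  out
}

#' Write a subset sweep as long-format and summary TSVs
#'
#' @param results output of [sweep_subsets()].
#' @param path_prefix writes `<prefix>_long.tsv` (size, iteration,
#'   predicted_type, match) and `<prefix>_summary.tsv` (size, accuracy).
#' @return the two paths, invisibly.
#' @export
write_sweep <- function(results, path_prefix) {
  long <- do.call(rbind, lapply(results, function(r) {
    data.frame(size = r$n_regions, iteration = seq_len(r$n_iterations),
               predicted_type = r$predictions,
               match = r$predictions == r$reference_prediction,
               stringsAsFactors = FALSE)
  }))
  p1 <- paste0(path_prefix, "_long.tsv")
  p2 <- paste0(path_prefix, "_summary.tsv")
  write.table(long, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(attr(results, "summary"), p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(p1, p2))
}

#' @export
print.subset_accuracy_result <- function(x, ...) {
  cat(sprintf("subset_accuracy: %d regions%s, %d iterations, accuracy %.3f (reference %s)\n",
              x$n_regions,
              if (!is.null(x$proportion))
                sprintf(" at %.0f%% enhancer proportion", 100 * x$proportion)
              else "",
              x$n_iterations, x$accuracy, x$reference_prediction))
  invisible(x)
}
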