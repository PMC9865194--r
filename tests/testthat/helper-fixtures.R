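# shared in-code fixtures for the test suite

# a small window set: n_chrom synthetic autosomes, nwin windows each
toy_windows <- function(n_chrom = 1, nwin = 3, window_size = 1e6) {
  sizes <- stats::setNames(rep(nwin * window_size, n_chrom),
                           sprintf("chr%d", seq_len(n_chrom)))
  build_windows(sizes, window_size = window_size, genome_build = "toy")
}

# planted-signal regression data: y equals (or is driven by) one column
planted_xy <- function(n = 500, p_noise = 30, seed = 1, exact = TRUE,
                       b = 1.0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * (p_noise + 1)), n, p_noise + 1)
    colnames(X) <- c(sprintf("noise%02d", seq_len(p_noise)), "driver")
    X <- X[, sort(colnames(X)), drop = FALSE]
    driver <- which(colnames(X) == "driver")
    y <- if (exact) X[, driver]
         else rpois(n, exp(b * scale(X[, driver])[, 1]))
    list(X = X, y = y, driver = "driver")
  })
}

# metadata for an arbitrary feature-id set: tissue taken from the id prefix
meta_for <- function(ids) {
  data.frame(feature_id = ids,
             tissue_type = sub("_.*$", "", ids),
             mark = "H3K4me1", source = "test",
             stringsAsFactors = FALSE)
}

# small planted two-tissue chromatin world for end-to-end ranking tests:
# tissueA drives y, tissueB is noise
small_world <- function(n = 400, seed = 1, b = 1.5) {
  withr::with_seed(seed, {
    za <- rnorm(n)
    zb <- rnorm(n)
    cols <- list(
      tissueA_H3K4me1 = rnbinom(n, mu = 100 * exp(0.5 * za), size = 10),
      tissueA_H3K27ac = rnbinom(n, mu = 100 * exp(0.5 * za), size = 10),
      tissueB_H3K4me1 = rnbinom(n, mu = 100 * exp(0.5 * zb), size = 10),
      tissueB_H3K27ac = rnbinom(n, mu = 100 * exp(0.5 * zb), size = 10))
    X <- do.call(cbind, cols)
    y <- rpois(n, exp(b * za))
    list(X = X, y = y, meta = meta_for(colnames(X)), driver = "tissueA")
  })
}
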