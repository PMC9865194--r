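test_that("enhancer-containing windows are flagged on >= 1 bp overlap", {
  ws <- toy_windows(nwin = 3)
  expect_equal(mark_enhancer_windows(ws, data.frame(chrom = "chr1",
                                                    start = 10, end = 20)),
               c(TRUE, FALSE, FALSE))
  # an enhancer spanning the window boundary flags both windows
  expect_equal(mark_enhancer_windows(ws, data.frame(chrom = "chr1",
                                                    start = 1e6 - 5, end = 1e6 + 5)),
               c(TRUE, TRUE, FALSE))
  expect_equal(mark_enhancer_windows(ws, NULL), rep(FALSE, 3))
})

test_that("enhancer flags equal a brute-force overlap scan", {
  ws <- toy_windows(n_chrom = 2, nwin = 3)
  withr::with_seed(31, {
    s <- sample(3e6 - 1e4, 60)
    enh <- data.frame(chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
                      start = s, end = s + sample(100:2e4, 60, replace = TRUE))
  })
  got <- mark_enhancer_windows(ws, enh)
  oracle <- vapply(seq_len(n_windows(ws)), function(w) {
    win <- ws$windows[w, ]
    any(enh$chrom == win$chrom & enh$start < win$end & enh$end > win$start)
  }, TRUE)
  expect_equal(got, oracle)
})

test_that("subset draws honour the masked/unmasked quota exactly", {
  ws <- toy_windows(n_chrom = 2, nwin = 10) # 20 windows
  mask <- rep(c(TRUE, FALSE), 10)

  # proportion 1 with enough masked windows: all draws masked
  idx <- sample_subset(ws, mask, n_total = 8, proportion = 1, seed = 1)
  expect_length(idx, 8)
  expect_true(all(mask[idx + 1]))

  # proportion 0: disjoint from the mask
  idx0 <- sample_subset(ws, mask, n_total = 8, proportion = 0, seed = 1)
  expect_true(all(!mask[idx0 + 1]))

  # shortfall: 50% of 10 wanted masked, only 3 exist -> 3 masked + 7 unmasked
  mask3 <- c(rep(TRUE, 3), rep(FALSE, 17))
  idx_s <- sample_subset(ws, mask3, n_total = 10, proportion = 0.5, seed = 2)
  expect_equal(sum(mask3[idx_s + 1]), 3)
  expect_equal(sum(!mask3[idx_s + 1]), 7)

  expect_error(sample_subset(ws, n_total = 21, seed = 1), "exceeds")
  expect_error(sample_subset(ws, mask = NULL, n_total = 5, proportion = 0.5),
               "mask")
})

test_that("quota arithmetic is exact for every n_total <= 12 on small universes", {
  ws <- toy_windows(n_chrom = 1, nwin = 12)
  for (n_masked in c(2, 5, 9)) {
    mask <- c(rep(TRUE, n_masked), rep(FALSE, 12 - n_masked))
    for (n_total in 1:12) {
      for (prop in c(0, 0.25, 0.5, 0.75, 1)) {
        idx <- sample_subset(ws, mask, n_total, prop,
                             seed = seed_derive(1, n_masked, n_total))
        expect_length(idx, n_total)
        expect_equal(anyDuplicated(idx), 0)
        want <- floor(prop * n_total + 0.5)
        got_masked <- sum(mask[idx + 1])
        n_unmasked <- 12 - n_masked
        # exact rule: min(want, available), then unmasked fill, then top-up
        expected_masked <- min(want, n_masked)
        if (n_total - expected_masked > n_unmasked)
          expected_masked <- n_total - n_unmasked
        expect_equal(got_masked, expected_masked)
      }
    }
  }
})

test_that("subset draws are deterministic per seed and free of the mask when unset", {
  ws <- toy_windows(n_chrom = 1, nwin = 10)
  i1 <- sample_subset(ws, n_total = 4, seed = 7)
  i2 <- sample_subset(ws, n_total = 4, seed = 7)
  expect_identical(i1, i2)
  expect_false(identical(i1, sample_subset(ws, n_total = 4, seed = 8)))
})

test_that("the full-window subset always reproduces the reference prediction", {
  w <- small_world(n = 120, seed = 33, b = 2)
  res <- subset_accuracy(w$y, w$X, w$meta,
                         boost_params(cv_folds = 5),
                         n_regions = 120, n_iterations = 3, seed = 1)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$reference_prediction, res$predictions[1])
})

test_that("subset sweeps are reproducible and summarised per size", {
  w <- small_world(n = 150, seed = 34, b = 2)
  sizes <- c(60, 100, 150)
  s1 <- sweep_subsets(w$y, w$X, w$meta, boost_params(cv_folds = 5),
                      sizes = sizes, n_iterations = 3, seed = 5)
  s2 <- sweep_subsets(w$y, w$X, w$meta, boost_params(cv_folds = 5),
                      sizes = sizes, n_iterations = 3, seed = 5)
  expect_identical(attr(s1, "summary"), attr(s2, "summary"))
  expect_equal(attr(s1, "summary")$size, sizes)
  expect_true(all(attr(s1, "summary")$accuracy >= 0 &
                  attr(s1, "summary")$accuracy <= 1))
  # the full-size entry is degenerate-exact
  expect_equal(attr(s1, "summary")$accuracy[3], 1.0)
  expect_error(sweep_subsets(w$y, w$X, w$meta, boost_params(),
                             sizes = c(100, 50), n_iterations = 2),
               "ascending")

  prefix <- file.path(withr::local_tempdir(), "sweep")
  write_sweep(s1, prefix)
  long <- read.table(paste0(prefix, "_long.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(long), length(sizes) * 3)
  summ <- read.table(paste0(prefix, "_summary.tsv"), header = TRUE, sep = "\t")
  expect_equal(summ$accuracy, attr(s1, "summary")$accuracy)
})
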