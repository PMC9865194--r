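test_that("variant counting respects the half-open window convention", {
  ws <- toy_windows(nwin = 3)
  # 1-based positions 1 and 1,000,000 both fall in window 0
  p <- count_mutations(data.frame(chrom = "chr1", pos = c(1, 1e6)), ws, "s1")
  expect_equal(p$counts, c(2, 0, 0))
  # 1,000,001 is the first base of window 1
  p2 <- count_mutations(data.frame(chrom = "chr1", pos = 1e6 + 1), ws)
  expect_equal(p2$counts, c(0, 1, 0))
  expect_equal(p2$n_total, 1)
  expect_error(count_mutations(data.frame(chrom = "chr1", pos = -5), ws),
               "positive")
  # unknown chromosomes are dropped with a message, not an error
  expect_message(
    p3 <- count_mutations(data.frame(chrom = c("chr1", "chrZ"), pos = c(1, 1)), ws),
    "dropped 1")
  expect_equal(p3$n_total, 1)
  expect_equal(p3$n_dropped, 1L)
})

test_that("variant counts match a per-variant linear-scan oracle", {
  ws <- toy_windows(n_chrom = 2, nwin = 3) # windows on chr1 and chr2, some dropped below
  withr::with_seed(11, {
    v <- data.frame(chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
                    pos = sample(3e6, 500, replace = TRUE))
  })
  p <- count_mutations(v, ws, "oracle")
  oracle <- numeric(n_windows(ws))
  for (r in seq_len(nrow(v))) {
    for (w in seq_len(n_windows(ws))) {
      win <- ws$windows[w, ]
      if (v$chrom[r] == win$chrom && v$pos[r] - 1 >= win$start &&
          v$pos[r] - 1 < win$end)
        oracle[w] <- oracle[w] + 1
    }
  }
  expect_equal(p$counts, oracle)
  expect_equal(p$n_total, sum(oracle))

  # permutation invariance and additivity over a disjoint split
  perm <- withr::with_seed(2, sample(nrow(v)))
  expect_equal(count_mutations(v[perm, ], ws)$counts, p$counts)
  a <- count_mutations(v[1:200, ], ws)
  b <- count_mutations(v[201:500, ], ws)
  expect_equal(a$counts + b$counts, p$counts)
})

test_that("read counting assigns intervals to the window holding their midpoint", {
  ws <- toy_windows(nwin = 3)
  reads <- data.frame(chrom = "chr1", start = c(0, 100, 5000),
                      end = c(200, 400, 5100))
  expect_equal(count_feature_reads(reads, ws), c(3, 0, 0))
  # straddling read with midpoint just right of the boundary: window 1 only
  strad <- data.frame(chrom = "chr1", start = 1e6 - 100, end = 1e6 + 300)
  expect_equal(count_feature_reads(strad, ws), c(0, 1, 0))
  expect_error(count_feature_reads(
    data.frame(chrom = "chr1", start = 10, end = 10), ws), "end <= start")
})

test_that("read tallies match a brute-force midpoint scan", {
  ws <- toy_windows(n_chrom = 2, nwin = 2)
  withr::with_seed(3, {
    s <- sample(2e6 - 1000, 1000, replace = TRUE)
    reads <- data.frame(chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
                        start = s, end = s + sample(100:900, 1000, replace = TRUE))
  })
  got <- count_feature_reads(reads, ws)
  oracle <- numeric(n_windows(ws))
  for (r in seq_len(nrow(reads))) {
    mid <- floor((reads$start[r] + reads$end[r]) / 2)
    for (w in seq_len(n_windows(ws))) {
      win <- ws$windows[w, ]
      if (reads$chrom[r] == win$chrom && mid >= win$start && mid < win$end)
        oracle[w] <- oracle[w] + 1
    }
  }
  expect_equal(got, oracle)
})

test_that("matrix assembly sorts columns and validates inputs", {
  ws <- toy_windows(nwin = 3)
  cols <- list(b_feat = c(1, 2, 3), a_feat = c(4, 5, 6))
  meta <- meta_for(c("a_feat", "b_feat"))
  m <- assemble_matrix(cols, meta, ws)
  expect_equal(colnames(m), c("a_feat", "b_feat"))
  expect_equal(unname(m[, "a_feat"]), c(4, 5, 6))
  expect_equal(nrow(m), 3)

  expect_error(assemble_matrix(list(a_feat = 1:2, b_feat = 1:3), meta, ws),
               "a_feat")
  expect_error(assemble_matrix(list(a_feat = 1:3, zz = 1:3), meta, ws), "zz")
  expect_error(
    assemble_matrix(stats::setNames(list(1:3, 1:3), c("a_feat", "a_feat")),
                    meta, ws),
    "duplicate")
})

test_that("profile aggregation is an element-wise sum with algebraic structure", {
  ws <- toy_windows(nwin = 3)
  mk <- function(counts, id) epiorigin:::new_mutation_profile(id, counts, ws)
  p1 <- mk(c(1, 0, 2), "a")
  p2 <- mk(c(0, 0, 1), "b")
  agg <- aggregate_profiles(list(p1, p2), "grp")
  expect_equal(agg$counts, c(1, 0, 3))
  expect_equal(agg$sample_id, "grp")
  expect_equal(aggregate_profiles(list(p1))$counts, p1$counts)

  # commutative / associative; matches an independent column-sum loop
  profs <- withr::with_seed(5, lapply(1:10, function(i)
    mk(rpois(3, 4), paste0("s", i))))
  agg10 <- aggregate_profiles(profs)
  oracle <- c(0, 0, 0)
  for (p in profs) oracle <- oracle + p$counts
  expect_equal(agg10$counts, oracle)
  expect_equal(aggregate_profiles(rev(profs))$counts, agg10$counts)
  left <- aggregate_profiles(list(aggregate_profiles(profs[1:3]),
                                  aggregate_profiles(profs[4:10])))
  expect_equal(left$counts, agg10$counts)

  ws2 <- toy_windows(nwin = 4)
  p_other <- epiorigin:::new_mutation_profile("c", rep(0, 4), ws2)
  expect_error(aggregate_profiles(list(p1, p_other)), "different window sets")
})

test_that("density, filtering and stratified sampling behave as specified", {
  ws <- toy_windows(nwin = 3)
  mk <- function(counts, id) epiorigin:::new_mutation_profile(id, counts, ws)
  expect_equal(per_mb_density(mk(c(2, 4, 6), "x")), 4.0)
  expect_equal(per_mb_density(mk(c(0, 0, 0), "x")), 0.0)
  # density of an aggregate equals the sum of member densities
  p1 <- mk(c(1, 2, 3), "a"); p2 <- mk(c(3, 0, 0), "b")
  expect_equal(per_mb_density(aggregate_profiles(list(p1, p2))),
               per_mb_density(p1) + per_mb_density(p2))

  profs <- list(mk(c(0, 0, 0), "lo"), mk(c(1, 1, 0), "mid"),
                mk(c(9, 9, 9), "hyper"))
  kept <- filter_by_density(profs, 0.25, 1.5)
  expect_equal(vapply(kept, function(p) p$sample_id, ""), "mid")
  expect_equal(attr(kept, "excluded_ids"), c("lo", "hyper"))
  expect_length(filter_by_density(profs, 0, Inf), 3)

  # brute-force filter agreement on random profiles
  rnd <- withr::with_seed(8, lapply(1:100, function(i)
    mk(rpois(3, runif(1, 0, 3)), paste0("r", i))))
  dens <- vapply(rnd, per_mb_density, 0)
  expect_equal(vapply(filter_by_density(rnd, 0.5, 2), function(p) p$sample_id, ""),
               vapply(rnd[dens >= 0.5 & dens <= 2], function(p) p$sample_id, ""))

  # stratified sampling: deterministic, respects per-bin quota
  sel1 <- stratified_density_sample(rnd, bin_width = 0.25, n_per_bin = 2, seed = 3)
  sel2 <- stratified_density_sample(rnd, bin_width = 0.25, n_per_bin = 2, seed = 3)
  expect_identical(sel1, sel2)
  bins_all <- floor(dens / 0.25)
  bins_sel <- floor(vapply(sel1, per_mb_density, 0) / 0.25)
  for (b in unique(bins_all)) {
    expect_equal(sum(bins_sel == b), min(2, sum(bins_all == b)))
  }
  # one profile per bin with quota 1 returns everything
  singles <- rnd[!duplicated(bins_all)]
  expect_length(stratified_density_sample(singles, 0.25, 1, seed = 1),
                length(singles))
})

test_that("profiles and matrices survive a disk round-trip", {
  ws <- toy_windows(nwin = 3)
  p <- count_mutations(data.frame(chrom = "chr1", pos = c(1, 2, 2.5e6)), ws, "rt")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(p2$counts, p$counts)
  expect_equal(p2$sample_id, "rt")
  expect_equal(p2$window_ref, p$window_ref)

  m <- assemble_matrix(list(a_feat = c(1, 0, 2), b_feat = c(5, 5, 5)),
                       meta_for(c("a_feat", "b_feat")), ws)
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, fm)
  m2 <- read_matrix(fm, ws)
  expect_equal(unclass(m2)[, ], unclass(m)[, ])
  expect_error(read_matrix(fm, toy_windows(nwin = 4)), "rows")
})
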