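#' Configuration for the synthetic planted-origin world
#'
#' The generator emulates the statistical structure the method assumes: each
#' tissue has a latent per-window chromatin profile; the tissue's features
#' are noisy negative-binomial renderings of that profile with within-tissue
#' correlation `rho`; one designated driver tissue's (standardized) latent
#' profile drives the per-window mutation rate on the log scale. Defaults
#' plant a strong, realistically sparse signal: 2128 windows, 8 tissues of
#' 8 features (64 tracks, seven marks cycled), rho = 0.9, effect b = -1
#' (active-chromatin depletion sign), baseline density 1 mutation per Mb
#' window (the normal-clone regime; stem cells sit nearer 0.1, tumors at
#' 5+), log-normal overdispersion sd 0.3, mean 500 reads per feature-window.
#'
#' @param n_windows retained windows.
#' @param n_tissues number of tissue/cell types.
#' @param features_per_tissue ChIP-seq tracks per tissue.
#' @param rho within-tissue correlation of feature latents, in `[0, 1)`.
#' @param driver_tissue planted origin; default the first tissue.
#' @param effect_size coefficient `b` on the standardized driver profile in
#'   the log mutation rate.
#' @param baseline_density target mean mutations per window.
#' @param mean_reads mean ChIP-seq reads per feature per window.
#' @param dispersion negative-binomial size for feature counts.
#' @param noise_sd sd of extra log-normal noise on the mutation rate.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_windows = 2128, n_tissues = 8, features_per_tissue = 8,
                       rho = 0.9, driver_tissue = NULL, effect_size = -1.0,
                       baseline_density = 1.0, mean_reads = 500,
                       dispersion = 10, noise_sd = 0.3, seed = 1) {
  stopifnot(n_windows >= 2, n_tissues >= 2, features_per_tissue >= 1,
            rho >= 0, rho < 1, baseline_density > 0, mean_reads > 0,
            dispersion > 0, noise_sd >= 0)
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  driver <- driver_tissue %||% tissues[1]
  if (!driver %in% tissues) stop("driver_tissue not among simulated tissues")
  structure(list(n_windows = as.integer(n_windows),
                 n_tissues = as.integer(n_tissues),
                 features_per_tissue = as.integer(features_per_tissue),
                 rho = rho, tissues = tissues, driver_tissue = driver,
                 effect_size = effect_size,
                 baseline_density = baseline_density,
                 mean_reads = mean_reads, dispersion = dispersion,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

sim_marks <- c("H3K27me3", "H3K9me3", "H3K27ac", "H3K36me3",
               "H3K4me1", "H3K4me3", "H3K9ac")

#' Simulate a chromatin matrix with tissue structure
#'
#' Per tissue, a standard-normal latent profile `u_t` is drawn over
#' windows; feature `f` of tissue `t` has latent `rho * u_t +
#' sqrt(1 - rho^2) * e_f` and counts drawn negative-binomially with
#' log-mean proportional to that latent. The driver tissue's latent (the
#' realized mutation-rate driver) is recorded in the truth object.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a `chromatin_matrix`-shaped windows x
#'   features matrix), `meta` (feature metadata), and `truth`
#'   (`driver_tissue`, `driver_feature_ids`, `driver_signal` = the latent
#'   profile, `latents` per tissue).
#' @export
simulate_chromatin <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_windows
  with_seed(seed_derive(config$seed, 7L), {
    latents <- sapply(config$tissues, function(t) rnorm(n))
    cols <- list()
    meta <- list()
    for (ti in seq_along(config$tissues)) {
      t <- config$tissues[ti]
      for (f in seq_len(config$features_per_tissue)) {
        id <- sprintf("%s_%s_r%d", t,
                      sim_marks[(f - 1) %% length(sim_marks) + 1],
                      (f - 1) %/% length(sim_marks) + 1)
        lat <- config$rho * latents[, ti] +
          sqrt(1 - config$rho^2) * rnorm(n)
        mu <- config$mean_reads * exp(0.5 * lat - 0.125)
        cols[[id]] <- rnbinom(n, size = config$dispersion, mu = mu)
        meta[[id]] <- data.frame(
          feature_id = id, tissue_type = t,
          mark = sim_marks[(f - 1) %% length(sim_marks) + 1],
          source = "synthetic", stringsAsFactors = FALSE)
      }
    }
    meta <- do.call(rbind, meta)
    rownames(meta) <- NULL
    ids <- sort(names(cols))
    m <- do.call(cbind, cols[ids])
    colnames(m) <- ids
    rownames(m) <- seq_len(n) - 1L
    class(m) <- c("chromatin_matrix", class(m))
    di <- match(config$driver_tissue, config$tissues)
    list(matrix = m, meta = meta,
         truth = list(driver_tissue = config$driver_tissue,
                      driver_feature_ids =
                        meta$feature_id[meta$tissue_type == config$driver_tissue],
                      driver_signal = latents[, di],
                      latents = latents))
  })
}

#' Simulate a mutation profile driven by the planted tissue
#'
#' Per-window counts are Poisson with log-mean `a + b * z + eps`, where `z`
#' is the standardized driver latent profile, `eps ~ N(0, noise_sd)`, and
#' the intercept `a = log(baseline_density) - b^2/2 - noise_sd^2/2` makes
#' the expected per-window density equal `baseline_density` exactly.
#'
#' @param chromatin output of [simulate_chromatin()].
#' @param config the same [sim_config()].
#' @param sample_id label for the profile.
#' @return a `mutation_profile` (with `window_ref` of the synthetic axis).
#' @export
simulate_mutations <- function(chromatin, config = sim_config(),
                               sample_id = "sim_sample") {
  z <- chromatin$truth$driver_signal
  z <- (z - mean(z)) / sd(z)
  b <- config$effect_size
  a <- log(config$baseline_density) - b^2 / 2 - config$noise_sd^2 / 2
  counts <- with_seed(seed_derive(config$seed, 13L, nchar(sample_id),
                                  sum(utf8ToInt(sample_id))), {
    eps <- rnorm(length(z), 0, config$noise_sd)
    rpois(length(z), exp(a + b * z + eps))
  })
  structure(list(sample_id = sample_id, counts = as.numeric(counts),
                 n_total = sum(counts), n_dropped = 0L,
                 window_ref = NA_character_),
            class = "mutation_profile")
}

#' Write a complete synthetic fixture tree
#'
#' Emits, under `dir`: `chrom_sizes.tsv`, `exclusions.bed`, `windows.bed`,
#' `matrix.tsv`, `metadata.tsv`, one `enhancers_<tissue>.bed` per tissue
#' (intervals placed inside the windows where that tissue's latent profile
#' is highest), one `variants_<sample>.tsv` per requested sample, and
#' `truth.json`. The windows are laid out on 22 synthetic autosomes; chrom
#' 1 carries one fully excluded extra window and chrom 2 a trailing partial
#' window, so rebuilding windows from `chrom_sizes.tsv` + `exclusions.bed`
#' through [build_windows()] reproduces `windows.bed` exactly. All files
#' parse back through the package's own readers.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param n_samples mutation profiles to emit.
#' @param window_size bp per window (default 1e6).
#' @param enhancer_fraction fraction of a tissue's top windows that get an
#'   enhancer interval.
#' @return invisibly, a list of the emitted paths plus the in-memory
#'   objects (`ws`, `chromatin`, `profiles`).
#' @export
write_fixture <- function(dir, config = sim_config(), n_samples = 1,
                          window_size = 1e6, enhancer_fraction = 0.2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$n_windows
  n_chrom <- 22L
  per <- rep(n %/% n_chrom, n_chrom) + c(rep(1L, n %% n_chrom),
                                         rep(0L, n_chrom - n %% n_chrom))
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  sizes <- per * window_size
  sizes[1] <- sizes[1] + window_size     # one extra, fully excluded window
  sizes[2] <- sizes[2] + window_size %/% 2 # trailing partial, dropped
  chrom_sizes <- data.frame(chrom = chroms, length = sizes)
  exclusions <- data.frame(chrom = "chr1",
                           start = (per[1]) * window_size,
                           end = (per[1] + 1) * window_size)

  p_sizes <- file.path(dir, "chrom_sizes.tsv")
  write.table(chrom_sizes, p_sizes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  p_excl <- file.path(dir, "exclusions.bed")
  write.table(format(exclusions, scientific = FALSE, trim = TRUE), p_excl,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  ws <- build_windows(chrom_sizes, exclusions, window_size = window_size,
                      genome_build = "synthetic")
  stopifnot(n_windows(ws) == n)
  p_win <- file.path(dir, "windows.bed")
  write_windows(ws, p_win)

  sim <- simulate_chromatin(config)
  m <- sim$matrix
  attr(m, "window_ref") <- window_fingerprint(ws)
  rownames(m) <- ws$windows$index
  p_mat <- file.path(dir, "matrix.tsv")
  write_matrix(m, p_mat)
  p_meta <- file.path(dir, "metadata.tsv")
  write_metadata(sim$meta, p_meta)

  # tissue-specific enhancers: short intervals centred in each tissue's
  # top-latent windows
  n_enh <- max(1L, as.integer(round(enhancer_fraction * n)))
  p_enh <- character(0)
  for (ti in seq_along(config$tissues)) {
    top <- order(sim$truth$latents[, ti], decreasing = TRUE)[seq_len(n_enh)]
    wdf <- ws$windows[top, , drop = FALSE]
    enh <- data.frame(chrom = wdf$chrom,
                      start = wdf$start + window_size %/% 2 - 500,
                      end = wdf$start + window_size %/% 2 + 500)
    enh <- enh[order(match(enh$chrom, chroms), enh$start), ]
    path <- file.path(dir, sprintf("enhancers_%s.bed", config$tissues[ti]))
    write.table(format(enh, scientific = FALSE, trim = TRUE), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    p_enh <- c(p_enh, path)
  }

  profiles <- list()
  p_var <- character(0)
  for (s in seq_len(n_samples)) {
    sid <- sprintf("sample%02d", s)
    cfg_s <- config
    cfg_s$seed <- seed_derive(config$seed, 17L, s)
    prof <- simulate_mutations(sim, cfg_s, sample_id = sid)
    prof$window_ref <- window_fingerprint(ws)
    profiles[[sid]] <- prof
    # scatter each window's count as uniform positions inside the window
    pos <- with_seed(seed_derive(config$seed, 19L, s), {
      wdf <- ws$windows[rep(seq_len(n), prof$counts), , drop = FALSE]
      data.frame(chrom = wdf$chrom,
                 pos = wdf$start + floor(runif(nrow(wdf)) * window_size) + 1)
    })
    pos <- pos[order(match(pos$chrom, chroms), pos$pos), ]
    path <- file.path(dir, sprintf("variants_%s.tsv", sid))
    write.table(format(pos, scientific = FALSE, trim = TRUE), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    p_var <- c(p_var, path)
  }

  p_truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(driver_tissue = sim$truth$driver_tissue,
                            driver_feature_ids = sim$truth$driver_feature_ids,
                            config = unclass(config)[setdiff(names(config),
                                                             "tissues")],
                            samples = names(profiles)),
                       p_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(chrom_sizes = p_sizes, exclusions = p_excl,
                 windows = p_win, matrix = p_mat, metadata = p_meta,
                 enhancers = p_enh, variants = p_var, truth = p_truth,
                 ws = ws, chromatin = sim, profiles = profiles))
}
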