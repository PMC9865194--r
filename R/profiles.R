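#' Count somatic variants per genomic window
#'
#' Aggregates variant positions into the retained windows of `ws`, yielding
#' a per-sample regional mutation profile. Positions are 1-based on input
#' (VCF convention) and converted internally to 0-based; a variant falls in
#' window `[start, end)` when `pos - 1` lies in it. Variants on unknown
#' chromosomes or in non-retained (excluded) regions are dropped and the
#' dropped total is reported via a message and the `n_dropped` field.
#'
#' @param variants data.frame whose first two columns are chromosome and
#'   1-based position (extra columns ignored), or a file path accepted by
#'   [read_variants()].
#' @param ws a `window_set`.
#' @param sample_id label stored on the profile.
#' @return an object of class `mutation_profile`: list with `sample_id`,
#'   `counts` (length `n_windows(ws)`), `n_total = sum(counts)`,
#'   `n_dropped`, and `window_ref`.
#' @export
count_mutations <- function(variants, ws, sample_id = "sample") {
  stopifnot(inherits(ws, "window_set"))
  if (is.character(variants) && length(variants) == 1)
    variants <- read_variants(variants)
  chrom <- as.character(variants[[1]])
  pos1 <- as.numeric(variants[[2]])
  if (any(pos1 <= 0)) stop("variant positions must be positive (1-based)")
  idx <- locate_windows(chrom, pos1 - 1, ws)
  n_drop <- sum(is.na(idx))
  if (n_drop > 0)
    message(sprintf("count_mutations: dropped %d variant(s) outside retained windows", n_drop))
  counts <- tabulate(idx[!is.na(idx)] + 1L, nbins = n_windows(ws))
  new_mutation_profile(sample_id, counts, ws, n_dropped = n_drop)
}

new_mutation_profile <- function(sample_id, counts, ws, n_dropped = 0L) {
  structure(list(sample_id = sample_id, counts = as.numeric(counts),
                 n_total = sum(counts), n_dropped = as.integer(n_dropped),
                 window_ref = window_fingerprint(ws)),
            class = "mutation_profile")
}

# map (chrom, 0-based pos) to retained window index; NA when not retained
locate_windows <- function(chrom, pos0, ws) {
  wsize <- ws$window_size
  key <- paste(chrom, pos0 %/% wsize)
  wkey <- paste(ws$windows$chrom, ws$windows$start %/% wsize)
  ws$windows$index[match(key, wkey)]
}

#' Read variant positions from a VCF or two-column TSV
#'
#' Only CHROM and POS are consumed. Files ending in `.vcf` (or containing
#' VCF header lines) are parsed as VCF; anything else as headerless
#' tab-separated chrom/pos.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `pos` (1-based).
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\\.vcf$", path) || startsWith(first, "##fileformat=VCF")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(chrom = vapply(fields, `[`, "", 1),
                     pos = as.numeric(vapply(fields, `[`, "", 2)),
                     stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, sep = "\t", header = FALSE,
                     colClasses = c("character", "numeric"),
                     col.names = c("chrom", "pos"))
  }
  if (anyNA(df$pos)) stop("unparseable variant position in ", path)
  df
}

#' Count ChIP-seq reads (intervals) per genomic window by midpoint
#'
#' Each interval is assigned to the window containing its midpoint
#' `floor((start + end) / 2)`, so a read straddling a window boundary is
#' counted exactly once. Intervals are 0-based half-open.
#'
#' @param intervals data.frame with columns chrom/start/end, or a BED3 path.
#' @param ws a `window_set`.
#' @return numeric vector of per-window counts, length `n_windows(ws)`.
#' @export
count_feature_reads <- function(intervals, ws) {
  stopifnot(inherits(ws, "window_set"))
  iv <- read_intervals(intervals)
  if (any(iv$end <= iv$start)) stop("interval with end <= start")
  mid <- floor((iv$start + iv$end) / 2)
  idx <- locate_windows(iv$chrom, mid, ws)
  tabulate(idx[!is.na(idx)] + 1L, nbins = n_windows(ws))
}

#' Assemble the windows-by-features chromatin matrix
#'
#' Columns are ordered by sorted feature id for determinism; every feature
#' must resolve to exactly one metadata row.
#'
#' @param columns named list of per-window count vectors (one per feature).
#' @param meta feature metadata data.frame with columns `feature_id`,
#'   `tissue_type`, `mark` and optionally `source`.
#' @param ws the `window_set` the columns were counted against.
#' @return a numeric matrix of class `chromatin_matrix` (windows x features)
#'   with `window_ref` and `meta` attributes.
#' @export
assemble_matrix <- function(columns, meta, ws) {
  stopifnot(inherits(ws, "window_set"), is.list(columns))
  ids <- names(columns)
  if (is.null(ids) || any(!nzchar(ids))) stop("columns must be named by feature_id")
  if (anyDuplicated(ids)) stop("duplicate feature_id: ",
                               ids[duplicated(ids)][1])
  meta <- validate_metadata(meta)
  missing <- setdiff(ids, meta$feature_id)
  if (length(missing))
    stop("feature(s) missing from metadata: ", paste(missing, collapse = ", "))
  n <- n_windows(ws)
  for (id in ids) {
    if (length(columns[[id]]) != n)
      stop(sprintf("feature '%s' has length %d, expected %d",
                   id, length(columns[[id]]), n))
    if (anyNA(columns[[id]])) stop(sprintf("feature '%s' contains NA", id))
  }
  ids <- sort(ids)
  m <- do.call(cbind, columns[ids])
  colnames(m) <- ids
  rownames(m) <- ws$windows$index
  structure(m, window_ref = window_fingerprint(ws),
            class = c("chromatin_matrix", class(m)))
}

validate_metadata <- function(meta) {
  stopifnot(is.data.frame(meta))
  need <- c("feature_id", "tissue_type", "mark")
  if (!all(need %in% names(meta)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$feature_id))
    stop("duplicated feature_id in metadata")
  if (is.null(meta$source)) meta$source <- "unspecified"
  meta
}

#' Sum mutation profiles into an aggregate profile
#'
#' Element-wise sum over windows, as used for aggregate-level
#' tissue-of-origin calls. All profiles must share the window axis.
#'
#' @param profiles list of `mutation_profile` objects.
#' @param group_id sample id for the aggregate.
#' @return a `mutation_profile`.
#' @export
aggregate_profiles <- function(profiles, group_id = "aggregate") {
  stopifnot(length(profiles) >= 1)
  refs <- vapply(profiles, function(p) p$window_ref, "")
  if (length(unique(refs)) != 1)
    stop("profiles were built against different window sets")
  counts <- Reduce(`+`, lapply(profiles, function(p) p$counts))
  structure(list(sample_id = group_id, counts = counts,
                 n_total = sum(counts),
                 n_dropped = sum(vapply(profiles, function(p) p$n_dropped, 0L)),
                 window_ref = refs[1]),
            class = "mutation_profile")
}

#' Mutation density per megabase-scale window
#'
#' Mean mutation count over the retained windows, i.e.
#' `n_total / n_windows`. With 1-Mb windows this is mutations per Mb.
#'
#' @param p a `mutation_profile`.
#' @return a single number.
#' @export
per_mb_density <- function(p) {
  stopifnot(inherits(p, "mutation_profile"), length(p$counts) > 0)
  p$n_total / length(p$counts)
}

#' Filter samples by mutation density
#'
#' Keeps profiles whose per-window density lies in `[min_density,
#' max_density]` (inclusive), preserving order. Used both to drop
#' hypermutators and to select clone-density windows.
#'
#' @param profiles list of `mutation_profile` objects.
#' @param min_density,max_density inclusive bounds.
#' @return the surviving profiles, with excluded sample ids in the
#'   `excluded_ids` attribute.
#' @export
filter_by_density <- function(profiles, min_density = 0, max_density = Inf) {
  stopifnot(min_density <= max_density)
  dens <- vapply(profiles, per_mb_density, 0)
  keep <- dens >= min_density & dens <= max_density
  out <- profiles[keep]
  attr(out, "excluded_ids") <-
    vapply(profiles[!keep], function(p) p$sample_id, "")
  out
}

#' Stratified random sample of profiles across density bins
#'
#' Bins profiles by density into `[k*bin_width, (k+1)*bin_width)` intervals
#' and draws up to `n_per_bin` profiles per occupied bin without
#' replacement, deterministically for a fixed seed. Mirrors clone selection
#' at fixed counts per 0.25 mutations/Mb interval.
#'
#' @param profiles list of `mutation_profile` objects.
#' @param bin_width density bin width (e.g. 0.25).
#' @param n_per_bin draws per bin (all available if fewer).
#' @param seed integer seed.
#' @return selected profiles, ordered by bin then original position.
#' @export
stratified_density_sample <- function(profiles, bin_width = 0.25,
                                      n_per_bin = 1, seed = 1) {
  stopifnot(bin_width > 0, n_per_bin >= 1)
  dens <- vapply(profiles, per_mb_density, 0)
  bin <- floor(dens / bin_width)
  picked <- integer(0)
  for (b in sort(unique(bin))) {
    members <- which(bin == b)
    k <- min(n_per_bin, length(members))
    sel <- with_seed(seed_derive(seed, 1009L, b), {
      if (length(members) == 1) members else sort(sample(members, k))
    })
    picked <- c(picked, sel)
  }
  profiles[picked]
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("mutation_profile '%s': %d mutations over %d windows (%.3f per window)\n",
              x$sample_id, x$n_total, length(x$counts), per_mb_density(x)))
  invisible(x)
}
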