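#' Build the retained set of fixed-width autosomal windows
#'
#' Tiles each autosome from position 0 in steps of `window_size` (1 Mb by
#' default), drops the trailing partial window, then drops any window whose
#' overlap with the (merged) exclusion intervals — centromeres, telomeres,
#' poorly mappable sequence — exceeds `excluded_fraction_max` of its width.
#' Retained windows get dense indices `0..N-1` in chromosome natural order
#' then start position; this index axis is shared by every mutation profile
#' and chromatin matrix built against the set.
#'
#' All coordinates are 0-based half-open (BED convention).
#'
#' @param chrom_sizes named numeric vector or two-column data.frame
#'   (chrom, length in bp) covering autosomes only (`chr1`..`chr22` or
#'   `1`..`22`).
#' @param exclusions `NULL`, a data.frame with columns chrom/start/end, or a
#'   BED3 file path. Intervals may overlap; they are merged internally.
#' @param window_size window width in bp.
#' @param excluded_fraction_max drop a window when its excluded-base
#'   fraction exceeds this value (default 0.5).
#' @param genome_build free-text label stored with the set.
#' @return an object of class `window_set`: list with `windows`
#'   (data.frame chrom/start/end/index), `window_size`, `genome_build`,
#'   `excluded_fraction_max`.
#' @export
#' @examples
#' ws <- build_windows(c(chr1 = 2.5e6), window_size = 1e6)
#' ws$windows
build_windows <- function(chrom_sizes, exclusions = NULL,
                          window_size = 1e6, excluded_fraction_max = 0.5,
                          genome_build = "GRCh37") {
  if (is.data.frame(chrom_sizes)) {
    sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  } else {
    sizes <- chrom_sizes
  }
  if (length(sizes) == 0) stop("chrom_sizes is empty")
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("chrom_sizes must be named by chromosome")
  bad <- names(sizes)[is.na(autosome_number(names(sizes)))]
  if (length(bad))
    stop("non-autosomal chromosome name(s): ", paste(bad, collapse = ", "))
  stopifnot(window_size > 0, excluded_fraction_max >= 0, excluded_fraction_max <= 1)

  sizes <- sizes[order(autosome_number(names(sizes)))]

  tiles <- lapply(names(sizes), function(ch) {
    n_full <- floor(sizes[[ch]] / window_size)
    if (n_full < 1) return(NULL)
    start <- (seq_len(n_full) - 1) * window_size
    data.frame(chrom = ch, start = start, end = start + window_size,
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, tiles)
  if (is.null(win) || nrow(win) == 0)
    stop("no chromosome is long enough for a single window")

  excl <- read_intervals(exclusions)
  if (!is.null(excl) && nrow(excl) > 0) {
    frac <- excluded_fraction(win, excl)
    win <- win[frac <= excluded_fraction_max, , drop = FALSE]
  }
  if (nrow(win) == 0) stop("all windows were excluded")
  win$index <- seq_len(nrow(win)) - 1L
  rownames(win) <- NULL

  structure(list(windows = win, window_size = as.numeric(window_size),
                 genome_build = genome_build,
                 excluded_fraction_max = excluded_fraction_max),
            class = "window_set")
}

# parse autosome names; NA for anything that is not chr1..chr22 / 1..22
autosome_number <- function(x) {
  num <- sub("^chr", "", x)
  n <- suppressWarnings(as.integer(num))
  n[!grepl("^(chr)?[0-9]+$", x)] <- NA_integer_
  n[!is.na(n) & (n < 1 | n > 22)] <- NA_integer_
  n
}

# fraction of each window covered by the merged exclusion intervals
excluded_fraction <- function(win, excl) {
  win_gr <- GenomicRanges::GRanges(win$chrom,
                                   IRanges::IRanges(win$start + 1, win$end))
  ex_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    excl$chrom, IRanges::IRanges(excl$start + 1, excl$end)))
  hits <- GenomicRanges::findOverlaps(win_gr, ex_gr)
  ov <- IRanges::pintersect(win_gr[S4Vectors::queryHits(hits)],
                            ex_gr[S4Vectors::subjectHits(hits)])
  covered <- rep(0, nrow(win))
  if (length(hits)) {
    tab <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(tab))] <- as.numeric(tab)
  }
  covered / (win$end - win$start)
}

# accept NULL, a chrom/start/end data.frame, or a BED3 path
read_intervals <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    df <- read.table(x, sep = "\t", header = FALSE, comment.char = "#",
                     col.names = c("chrom", "start", "end"),
                     colClasses = c("character", "numeric", "numeric"))
    return(df)
  }
  if (is.data.frame(x)) {
    df <- x[, 1:3]
    names(df) <- c("chrom", "start", "end")
    df$chrom <- as.character(df$chrom)
    return(df)
  }
  stop("intervals must be NULL, a data.frame, or a BED file path")
}

#' Write / read a window set
#'
#' The on-disk format is a BED-like TSV: `#`-prefixed metadata lines
#' (window size, genome build, exclusion threshold) followed by
#' chrom/start/end/index rows, no column header. Writing then reading
#' reproduces the set exactly and the bytes are stable across runs.
#'
#' @param ws a `window_set`.
#' @param path file path.
#' @return `write_windows` returns `path` invisibly; `read_windows` returns
#'   a `window_set`.
#' @export
write_windows <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf("#window_size=%s\n#genome_build=%s\n#excluded_fraction_max=%s\n",
                 format(ws$window_size, scientific = FALSE),
                 ws$genome_build, format(ws$excluded_fraction_max))
  writeChar(hdr, con, eos = NULL)
  body <- sprintf("%s\t%s\t%s\t%d\n", ws$windows$chrom,
                  format(ws$windows$start, scientific = FALSE, trim = TRUE),
                  format(ws$windows$end, scientific = FALSE, trim = TRUE),
                  ws$windows$index)
  writeChar(paste(body, collapse = ""), con, eos = NULL)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) != 4 || anyNA(suppressWarnings(as.numeric(f[2:4]))))
      stop(sprintf("malformed window row at line %d", body_idx[k]))
    if (as.numeric(f[3]) <= as.numeric(f[2]))
      stop(sprintf("end <= start at line %d", body_idx[k]))
  }
  win <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = as.numeric(vapply(fields, `[`, "", 2)),
    end = as.numeric(vapply(fields, `[`, "", 3)),
    index = as.integer(vapply(fields, `[`, "", 4)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(win$index))
    stop("duplicated window index in ", path)
  if (!identical(win$index, seq_len(nrow(win)) - 1L))
    stop("window indices must be dense 0..N-1 in file order")
  wsize <- as.numeric(meta[["window_size"]] %||% (win$end[1] - win$start[1]))
  if (any(win$end - win$start != wsize))
    stop("window width inconsistent with window_size")
  structure(list(windows = win, window_size = wsize,
                 genome_build = meta[["genome_build"]] %||% "unknown",
                 excluded_fraction_max =
                   as.numeric(meta[["excluded_fraction_max"]] %||% NA)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows of %s bp on %d chromosome(s) [%s]\n",
              nrow(x$windows), format(x$window_size, scientific = FALSE),
              length(unique(x$windows$chrom)), x$genome_build))
  invisible(x)
}

#' Number of retained windows
#' @param ws a `window_set`.
#' @return integer count.
#' @export
n_windows <- function(ws) nrow(ws$windows)
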