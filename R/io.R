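#' Read and write chromatin matrices, metadata and profiles
#'
#' Plain-TSV persistence for the pipeline's tables. The chromatin matrix is
#' written with the window index as row key and feature ids as the header;
#' metadata as a four-column TSV (feature_id, tissue_type, mark, source);
#' a mutation profile as a two-column TSV (window index, count) with the
#' sample id in a `#` header line.
#'
#' @param m a `chromatin_matrix`.
#' @param path file path.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(window = rownames(m) %||% (seq_len(nrow(m)) - 1L),
                   as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @param ws optional `window_set`; when given, row count is validated and
#'   the matrix carries its fingerprint.
#' @export
read_matrix <- function(path, ws = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyNA(m)) stop("chromatin matrix contains missing cells")
  if (!is.null(ws)) {
    if (nrow(m) != n_windows(ws))
      stop(sprintf("matrix has %d rows but window set has %d",
                   nrow(m), n_windows(ws)))
    attr(m, "window_ref") <- window_fingerprint(ws)
  }
  class(m) <- c("chromatin_matrix", class(m))
  m
}

#' @rdname matrix_io
#' @param meta feature metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  write.table(meta[, c("feature_id", "tissue_type", "mark", "source")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_metadata <- function(path) {
  validate_metadata(read.table(path, sep = "\t", header = TRUE,
                               colClasses = "character"))
}

#' @rdname matrix_io
#' @param p a `mutation_profile`.
#' @export
write_profile <- function(p, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#sample_id=%s", p$sample_id), con)
  writeLines(sprintf("#window_ref=%s", p$window_ref), con)
  write.table(data.frame(window = seq_along(p$counts) - 1L, count = p$counts),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta <- list()
  for (ml in grep("^#", lines, value = TRUE)) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- read.table(text = lines[!grepl("^#", lines)], sep = "\t", header = TRUE)
  structure(list(sample_id = meta[["sample_id"]] %||% "sample",
                 counts = as.numeric(df$count), n_total = sum(df$count),
                 n_dropped = 0L,
                 window_ref = meta[["window_ref"]] %||% NA_character_),
            class = "mutation_profile")
}

#' Optional per-column total-count scaling of a chromatin matrix
#'
#' Rescales every feature column to a common total (the mean column sum).
#' Tree rankers are insensitive to monotone per-column transforms, so this
#' is off by default and provided only for cross-dataset comparability.
#'
#' @param m a `chromatin_matrix`.
#' @return the rescaled matrix.
#' @export
scale_columns <- function(m) {
  tot <- colSums(m)
  if (any(tot == 0)) stop("cannot scale a feature with zero total count")
  target <- mean(tot)
  out <- sweep(unclass(m), 2, tot / target, "/")
  attributes(out) <- attributes(m)[c("dim", "dimnames", "window_ref")]
  class(out) <- c("chromatin_matrix", "matrix", "array")
  out
}
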