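#' Derive a reproducible sub-seed
#'
#' Mixes a base seed with any number of integer labels (stage tags, sizes,
#' iteration counters) through a splitmix-style hash, returning a seed in
#' `[0, 2^31 - 1)`. Extending the label stream never changes seeds derived
#' from different labels, so adding subset sizes or extra iterations to an
#' analysis leaves previously drawn random streams untouched.
#'
#' @param seed integer base seed.
#' @param ... integer labels mixed into the derivation, in order.
#' @return a single integer seed.
#' @export
#' @examples
#' seed_derive(1, 100, 3)
seed_derive <- function(seed, ...) {
  parts <- c(seed, ...)
  if (any(!is.finite(parts))) stop("seed labels must be finite")
  .derive_seed_cpp(as.numeric(parts))
}

# Run code under a temporary R RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Compact fingerprint of a window set, used to refuse mixing profiles or
# matrices built against different window axes.
window_fingerprint <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  df <- ws$windows
  sprintf("ws:%d:%d:%s", nrow(df), ws$window_size,
          .derive_seed_cpp(as.numeric(c(
            nrow(df), ws$window_size,
            sum(df$start %% 2147483647), sum(df$end %% 2147483647),
            sum(utf8ToInt(paste(unique(df$chrom), collapse = ",")))
          ))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
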