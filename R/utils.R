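#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Simulation functions draw from per-entity substreams so that, e.g.,
#' adding readers does not perturb the case-level draws. Each substream is
#' seeded by hashing a string label together with the master seed. The hash
#' is a plain polynomial rolling hash over the UTF-8 code points, kept below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param seed master seed (integer).
#' @param label character label naming the substream.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  p <- 2147480009  # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% p
  as.integer((abs(seed) %% p + h * 1009) %% p)
}

#' Evaluate an expression with a local RNG state
#'
#' Saves and restores `.Random.seed` so simulator internals do not disturb
#' the caller's random number stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Round only at the reporting boundary
#'
#' Percentages in exported tables are rounded to one decimal; internal
#' values keep full precision.
#' @param x proportion in [0, 1].
#' @param digits decimals kept on the percentage scale.
#' @return numeric percentage.
#' @export
as_percent <- function(x, digits = 1) round(100 * x, digits)

log_stage <- function(..., quiet = FALSE) {
  if (!quiet) message(sprintf(...))
  invisible(NULL)
}
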