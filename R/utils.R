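#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, then restores the caller's RNG state so that
#' seeded package functions do not perturb the user's random stream. A `NULL`
#' seed evaluates `expr` under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named substream seed from a master seed
#'
#' One master seed fans out to independent, reproducible substreams (specimen
#' simulation, tree simulation, grafting, null models, permutations,
#' subsampling) so that changing the draw count of one stage cannot silently
#' shift another stage's random numbers. The derived seed is a deterministic
#' 31-bit hash of the master seed and the stream name.
#'
#' @param master integer master seed.
#' @param name character stream name, e.g. `"nulls"`.
#' @return a positive integer seed < 2^31.
#' @export
#' @examples
#' substream_seed(1, "nulls")
substream_seed <- function(master, name) {
  stopifnot(length(master) == 1, is.finite(master), is.character(name))
  h <- as.double(master) %% 2147483647
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# shared input check: non-negative, finite, numeric count vector
check_counts <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be a non-negative finite numeric vector")
  }
  counts
}
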