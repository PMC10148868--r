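`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under `seed` without clobbering the caller's RNG stream.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the package (the
#' heavy lifting on whole genomes stays in compiled code).
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GGCCGG")  # "CCGGCC"
revcomp <- function(x) {
  vapply(x, function(s) cpp_revcomp(toupper(s)), character(1), USE.NAMES = FALSE)
}
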