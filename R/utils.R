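#' @useDynLib vesselssl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_binary <- function(x) all(x == 0 | x == 1)

#' Independent reproducible RNG streams
#'
#' Training consumes randomness from several logically independent sources
#' (weight initialization, labeled sampling, unlabeled sampling, augmentation).
#' Each source gets its own stream so that, e.g., a run that never touches the
#' unlabeled stream draws exactly the same labeled batches as one that does.
#' A stream is a mutable environment holding a saved `.Random.seed`; drawing
#' swaps it in, evaluates, and swaps it back out.
#'
#' @param seed integer seed for this stream.
#' @return an environment of class `vssl_rng`.
#' @keywords internal
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  class(e) <- "vssl_rng"
  e
}

#' Evaluate an expression under a stream's RNG state
#' @param stream a [rng_stream()] object.
#' @param expr expression to evaluate.
#' @keywords internal
#' @export
with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

# Derive a deterministic 31-bit sub-seed from a parent seed and a stream tag.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}
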