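#' @keywords internal
#' @useDynLib tugfall, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All stochastic operations in the package route through
# this so that results are reproducible and independent of call order.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
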