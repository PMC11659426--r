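#' @useDynLib commassembly, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dist rnorm rlnorm rmultinom runif sd setNames lm
#' @importFrom utils read.table write.table
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Lower-triangle (column-major, i > j) unfold of a square matrix.
lower_tri_vec <- function(m) m[lower.tri(m)]

stop2 <- function(...) stop(..., call. = FALSE)
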