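#' @useDynLib ecgage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif predict quantile median sd approx spline fft
#' @importFrom stats setNames
#' @importFrom graphics abline
#' @importFrom utils read.csv write.csv head tail modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# If seed is NULL the expression runs against the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ecg <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ecg("`%s` must be a single finite number", name)
  if (strict && x <= lower) stop_ecg("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict && x < lower) stop_ecg("`%s` must be >= %g (got %g)", name, lower, x)
  invisible(x)
}
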