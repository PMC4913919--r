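#' @importFrom methods new is validObject slot
#' @importFrom stats var sd cor prcomp hclust as.dist quantile phyper pt
#'   p.adjust rnorm runif setNames ks.test optim ppoints
#' @exportMethod show
#' @importFrom Rcpp evalCpp
#' @useDynLib oncomap, .registration = TRUE
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed: lets each pipeline stage reseed independently of
# the others while being fully determined by the master seed. Kept below 2^31.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must lie in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
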