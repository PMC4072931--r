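#' @keywords internal
"_PACKAGE"

#' @importFrom stats var median ave rnorm rlnorm rbinom rnbinom rpois runif
#'   rbeta wilcox.test p.adjust pt cor setNames complete.cases quantile
#'   aggregate
#' @importFrom utils read.delim write.table head
NULL

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All simulation entry points route their randomness through this helper so
## that no function leaves a footprint on the global stream.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Derive a child seed from a base seed and a stage offset, staying < 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 101 + k * 7919) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
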