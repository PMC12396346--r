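#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois rnbinom runif rgamma sd cor p.adjust
#'   nls coef resid optim lowess approx median quantile rbinom setNames
#'   aggregate
#' @importFrom utils read.table write.table read.csv write.csv head tail
NULL

abort <- function(..., class = "dmgquant_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) abort(..., class = "dmgquant_validation_error")
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && abs(x - round(x)) < 1e-9

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `expr` under a locally-set RNG seed, restoring global RNG state.
# All stochastic code in the package funnels through this so that identical
# (config, seed) pairs give byte-identical output regardless of caller state.
with_seed <- function(seed, expr) {
  assert_that(is_count(seed) || (is_number(seed) && seed == 0),
              "seed must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# sample() without the length-1 surprise
sample_safe <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}
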