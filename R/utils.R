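#' @importFrom stats quantile rnorm runif sd dbinom pbinom
#' @importFrom methods new validObject is slot slotNames
NULL

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable hash of an R object (used for config provenance stamps).
configHash <- function(x) rlang::hash(x)

#' Round a fraction to the percent convention used in reports
#'
#' Fractions are reported as percentages with one decimal; ratios with three
#' decimals. Helper used by the reporting layer.
#' @param x numeric fraction in [0, 1]
#' @return numeric percentage rounded to one decimal
#' @keywords internal
asPercent <- function(x) round(100 * x, 1)

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
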