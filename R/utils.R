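# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' All stochastic operations in covbias take an explicit `seed` argument and
#' evaluate under a locally scoped RNG, so no function mutates the caller's
#' `.Random.seed`.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

# 0-based half-open [start, end) -> IRanges (1-based closed)
ir0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# IRanges -> data.table with 0-based half-open start/end
dt0 <- function(ir) {
  data.table::data.table(start = BiocGenerics::start(ir) - 1L,
                         end = BiocGenerics::end(ir))
}

# Sorted, merged 0-based intervals from start/end vectors (may be empty).
merge_intervals0 <- function(start, end) {
  if (length(start) == 0L) {
    return(data.table::data.table(start = integer(0), end = integer(0)))
  }
  dt0(IRanges::reduce(ir0(start, end)))
}

#' @importFrom stats median sd mad IQR quantile rpois runif rnorm rbinom
#'   setNames complete.cases cor pt rmultinom
#' @importFrom utils head tail packageVersion
NULL
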