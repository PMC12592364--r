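#' @importFrom stats cor eigen rnorm rpois runif rgeom rnbinom sd pnorm
#' @importFrom stats p.adjust pwilcox quantile
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() without the call, used for all user-facing validation
fail <- function(...) stop(..., call. = FALSE)

check_that <- function(cond, ...) if (!isTRUE(cond)) fail(...)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# All generators are pure functions of (args, seed): RNG state is scoped with
# withr so callers' streams are never consumed.
with_seed <- function(seed, code) {
  check_that(is_count(seed), "`seed` must be a single non-negative integer")
  withr::with_seed(as.integer(seed), code)
}

# deterministic child seed < 2^31 for staged pipelines
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * k) %% 2147483629
}

# coefficient of variation, the ICE convergence statistic
cv <- function(x) stats::sd(x) / mean(x)
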