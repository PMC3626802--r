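#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic entry points funnel through this so that every generator and
# multistart optimiser is a pure function of (arguments, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

uex_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "uexpress_error")))
}

# schema / value / usage / consistency error helpers
stop_schema      <- function(fmt, ...) uex_stop("uexpress_schema_error", fmt, ...)
stop_value       <- function(fmt, ...) uex_stop("uexpress_value_error", fmt, ...)
stop_usage       <- function(fmt, ...) uex_stop("uexpress_usage_error", fmt, ...)
stop_consistency <- function(fmt, ...) uex_stop("uexpress_consistency_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

LOG2 <- log(2)
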