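#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper predict quantile runif rnorm
#' @importFrom utils read.delim write.table packageVersion
NULL

# abort with a classed condition so callers can test errorClass
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("enrichIFS_format_error", "error")))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("enrichIFS_domain_error", "error")))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic package code funnels through this so that a user's session
# RNG is never disturbed and results are reproducible from integer seeds.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_domain("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a per-stage seed from a global one (kept below 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
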