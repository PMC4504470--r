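#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist optim pchisq plogis rbinom rexp rlnorm rnorm runif sd setNames
#' @importFrom utils combn head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
# All stochastic entry points funnel through this so that identical
# (inputs, seed) pairs give identical outputs.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# significance stars following the convention of the printed tables
signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}
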