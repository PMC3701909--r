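# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream when `seed` is given, leaving the
# caller's RNG state untouched. With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop_smkin <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "smkin_error")))
}

warn_smkin <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "smkin_warning")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Two-significant-figure rounding used when reporting stoichiometries.
signif2 <- function(x) signif(x, 2L)
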