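# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ..., class = "mmspike_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ...) {
  rlang::warn(sprintf(fmt, ...))
}

check_numeric <- function(x, arg = deparse(substitute(x)), min_len = 1L,
                          finite = TRUE) {
  if (!is.numeric(x)) stopf("`%s` must be numeric.", arg)
  if (length(x) < min_len) {
    stopf("`%s` must have at least %d values (got %d).",
          arg, min_len, length(x), class = "mmspike_degenerate_input")
  }
  if (finite && any(!is.finite(x))) {
    stopf("`%s` contains missing or non-finite values.", arg,
          class = "mmspike_missing_data")
  }
  invisible(x)
}

check_scalar <- function(x, arg = deparse(substitute(x)), positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number.", arg)
  }
  if (positive && x <= 0) {
    stopf("`%s` must be > 0 (got %g).", arg, x, class = "mmspike_parameter_error")
  }
  invisible(x)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Population (1/n) variance; the Poincare descriptors depend on this choice.
var_pop <- function(x) mean((x - mean(x))^2)

task_levels <- function() c("resting", "drawing", "pointing", "peg")
condition_levels <- function() c("control", "pain")
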