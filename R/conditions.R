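# Classed conditions so callers can distinguish bad parameters from runtime
# pathologies (variance blow-up, extinction, zero-variance series).

mat_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "matevolve_error")))
}

param_error <- function(msg) mat_stop(msg, "matevolve_param_error")

divergence_error <- function(msg, generation = NA_integer_) {
  mat_stop(msg, "matevolve_divergence", generation = generation)
}

extinction_error <- function(msg, generation = NA_integer_) {
  mat_stop(msg, "matevolve_extinction", generation = generation)
}

degenerate_error <- function(msg) mat_stop(msg, "matevolve_degenerate")

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    param_error(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    param_error(sprintf(
      "'%s' = %g violates %s%g, %g%s", name, x,
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]"))
  invisible(x)
}
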