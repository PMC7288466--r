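# Error helpers. Every user-facing failure carries a subclass of
# "orimin_error" so callers (and the CLI) can react by condition class:
#   orimin_error_domain       -- an input is outside its mathematical domain
#   orimin_error_inconsistent -- two observations contradict each other
#   orimin_error_labeling     -- labeled fraction too low for the S-phase model
#   orimin_error_config       -- a simulation configuration the model excludes
#   orimin_error_io           -- malformed or unresolvable input data

abort_domain <- function(message, ...) {
  rlang::abort(message, class = c("orimin_error_domain", "orimin_error"), ...)
}

abort_inconsistent <- function(message, ...) {
  rlang::abort(message, class = c("orimin_error_inconsistent", "orimin_error"), ...)
}

abort_labeling <- function(message, ...) {
  rlang::abort(message, class = c("orimin_error_labeling", "orimin_error"), ...)
}

abort_config <- function(message, ...) {
  rlang::abort(message, class = c("orimin_error_config", "orimin_error"), ...)
}

abort_io <- function(message, ...) {
  rlang::abort(message, class = c("orimin_error_io", "orimin_error"), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain(sprintf("`%s` must be a single finite number.", name))
  }
  lo_bad <- if (strict_min) x <= min else x < min
  hi_bad <- if (strict_max) x >= max else x > max
  if (lo_bad || hi_bad) {
    abort_domain(sprintf(
      "`%s` must be in %s%s, %s%s; got %g.",
      name,
      if (strict_min) "(" else "[", format(min),
      format(max), if (strict_max) ")" else "]",
      x
    ))
  }
  invisible(x)
}

check_fraction <- function(x, name, allow_one = TRUE) {
  check_number(x, name, min = 0, max = 1, strict_max = !allow_one)
}

is_wholeish <- function(x, tol = 1e-6) {
  is.finite(x) & abs(x - round(x)) <= tol
}
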