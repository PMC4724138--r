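# Internal helpers shared across modules.

# round() uses round-half-to-even; published tables round half away from
# zero, so reported values go through this instead.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Validate a numeric scalar/vector; `name` appears in the error message.
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

check_frequency <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) & is.finite(x) &
    if (open) (x > 0 & x < 1) else (x >= 0 & x <= 1)
  if (!all(ok)) {
    stop(sprintf("'%s' must be a frequency in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
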