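# Classed conditions used across the package. Every user-facing failure mode
# carries a class so callers (and tests) can discriminate programmatically:
#   dl_invalid_input  - argument validation failures
#   dl_degenerate     - degenerate measurement (zero intensity, zero area, ...)
#   dl_fit_error      - curve fit could not be performed or did not converge
#   dl_numeric_error  - iterative solver failure
#   dl_lookup_error   - keyed join failure (e.g. fragment id missing)
#   dl_config_error   - bad run configuration / pattern set

dl_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "dl_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

dl_warn <- function(message, class) {
  warning(structure(
    class = c(class, "dl_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stopifnot_finite <- function(x, name, non_negative = FALSE, positive = FALSE) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    dl_abort(sprintf("`%s` must be finite numeric", name), "dl_invalid_input")
  }
  if (non_negative && any(x < 0)) {
    dl_abort(sprintf("`%s` must be non-negative", name), "dl_invalid_input")
  }
  if (positive && any(x <= 0)) {
    dl_abort(sprintf("`%s` must be strictly positive", name), "dl_invalid_input")
  }
  invisible(x)
}
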