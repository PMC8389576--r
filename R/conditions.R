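# Classed conditions so callers (and the CLI) can map failures to exit codes.

pk_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "pamkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

pk_warn <- function(msg, class = "pamkit_warning") {
  warning(structure(
    class = c(class, "pamkit_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Argument checks used throughout; `what` names the offending argument.
check_number <- function(x, what, lower = -Inf, upper = Inf,
                         class = "pamkit_validation_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    pk_stop(sprintf("`%s` must be a single finite number", what), class)
  }
  if (x < lower || x > upper) {
    pk_stop(sprintf("`%s` = %g must be in [%g, %g]", what, x, lower, upper),
            class)
  }
  invisible(x)
}
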