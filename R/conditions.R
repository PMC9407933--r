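# Structured conditions so callers (and the CLI) can map failures to exit codes:
# validation errors are user-input problems, schema errors are file problems,
# coverage errors are a validation subclass raised when a model lacks the
# measurement rays an operation needs.

icz_abort <- function(message, class) {
  stop(structure(
    class = c(class, "icz_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

icz_validation_error <- function(message) {
  icz_abort(message, "icz_validation_error")
}

icz_schema_error <- function(message) {
  icz_abort(message, "icz_schema_error")
}

icz_coverage_error <- function(message) {
  icz_abort(message, c("icz_coverage_error", "icz_validation_error"))
}

icz_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "icz_warning")))
}

# is.numeric + finite scalar check used throughout validation
is_num <- function(x, n = 1L) {
  is.numeric(x) && length(x) == n && all(is.finite(x))
}
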