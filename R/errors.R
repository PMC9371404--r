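# Classed conditions so the CLI can map failures onto exit codes
# (configuration/validation problems vs. numerical failures mid-run).

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("assoclearn_config_error", "error", "condition")))
}

stop_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("assoclearn_numeric_error", "error", "condition")))
}

check_positive_scalar <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop_config("`%s` must be a single finite %s number (got %s)",
                name, if (strict) "positive" else "non-negative", deparse(x))
  }
  invisible(TRUE)
}
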