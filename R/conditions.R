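# Classed conditions so callers (and the CLI) can map failures to exit codes:
# configuration/validation problems vs. model-regime/solver problems.

abort_config <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("aortaflow_config_error", "aortaflow_error", "error")))
}

abort_domain <- function(msg) {
  stop(errorCondition(msg, class = c("aortaflow_domain_error", "aortaflow_error", "error")))
}

abort_regime <- function(msg, data = NULL) {
  stop(errorCondition(msg, data = data,
                      class = c("aortaflow_regime_error", "aortaflow_error", "error")))
}

abort_fit <- function(msg, data = NULL) {
  stop(errorCondition(msg, data = data,
                      class = c("aortaflow_fit_error", "aortaflow_regime_error",
                                "aortaflow_error", "error")))
}

warn_model <- function(msg) {
  warning(warningCondition(msg, class = c("aortaflow_warning", "warning")))
}

stopifnot_scalar <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_domain(sprintf("'%s' must be a single non-missing number", name))
  if (finite && !is.finite(x))
    abort_domain(sprintf("'%s' must be finite", name))
  if (positive && x <= 0)
    abort_domain(sprintf("'%s' must be > 0 (got %g)", name, x))
  invisible(x)
}
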