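#' Condition helpers
#'
#' All user-facing errors carry a subclass so callers (and the command-line
#' wrapper) can map failures to exit codes: configuration problems,
#' cross-file integrity problems, and missing upstream-stage outputs.
#'
#' @name crecascade-conditions
#' @keywords internal
NULL

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crecascade_config_error", "crecascade_error")))
}

stop_integrity <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crecascade_integrity_error", "crecascade_error")))
}

stop_dependency <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crecascade_dependency_error", "crecascade_error")))
}

stop_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crecascade_parse_error", "crecascade_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
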