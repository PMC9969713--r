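## Classed conditions so callers (and tests) can distinguish failure modes.

.pscStop <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "pscError", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
configurationError <- function(message) .pscStop("configurationError", message)

#' @noRd
validationError <- function(message) .pscStop("validationError", message)

#' @noRd
degenerateInputError <- function(message) .pscStop("degenerateInputError", message)

#' @noRd
undefinedRatioError <- function(message) .pscStop("undefinedRatioError", message)

#' @noRd
noOverlapError <- function(message) .pscStop("noOverlapError", message)

#' @noRd
formatError <- function(message) .pscStop("formatError", message)

#' @noRd
emptyRenderError <- function(message) .pscStop("emptyRenderError", message)
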