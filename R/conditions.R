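#' @keywords internal
#' @importFrom dplyr .data
"_PACKAGE"

# Classed conditions so callers (and the pipeline driver) can distinguish
# bad configuration from bad data from strata that are simply too small.

abort_exofrag <- function(message, class) {
  stop(structure(
    class = c(class, "exofrag_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

validation_error <- function(message) {
  abort_exofrag(message, "exofrag_validation_error")
}

format_error <- function(message) {
  abort_exofrag(message, "exofrag_format_error")
}

config_error <- function(message) {
  abort_exofrag(message, "exofrag_config_error")
}

insufficient_data_error <- function(message) {
  abort_exofrag(message, "exofrag_insufficient_data_error")
}

undefined_result_error <- function(message) {
  abort_exofrag(message, "exofrag_undefined_result_error")
}
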