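# Classed conditions so callers can distinguish configuration mistakes,
# malformed files and numerically degenerate geometry.

abort_mdh <- function(message, class) {
  stop(structure(
    class = c(paste0("mdh_", class, "_error"), "mdh_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_format     <- function(message) abort_mdh(message, "format")
abort_config     <- function(message) abort_mdh(message, "config")
abort_empty      <- function(message) abort_mdh(message, "empty")
abort_degenerate <- function(message) abort_mdh(message, "degenerate")
abort_shape      <- function(message) abort_mdh(message, "shape")
abort_param      <- function(message) abort_mdh(message, "param")
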