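# Typed conditions used across the package. Validation failures and undefined
# metrics are distinguishable by class so callers can handle them separately.

abort_validation <- function(msg) {
  stop(structure(
    class = c("ac4c_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_undefined_metric <- function(msg) {
  stop(structure(
    class = c("ac4c_undefined_metric", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
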