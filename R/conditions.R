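# Structured error conditions so callers (and tests) can distinguish bad
# input files, malformed metadata, contract violations and pairing problems.

calscan_abort <- function(message, class) {
  stop(structure(
    class = c(class, "calscan_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_input      <- function(msg) calscan_abort(msg, "calscan_input_error")
abort_schema     <- function(msg) calscan_abort(msg, "calscan_schema_error")
abort_validation <- function(msg) calscan_abort(msg, "calscan_validation_error")
abort_pairing    <- function(msg) calscan_abort(msg, "calscan_pairing_error")
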