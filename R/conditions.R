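## Classed error conditions so callers (and tests) can distinguish failure
## modes: format errors carry file/line context, leakage guards are hard
## refusals, consistency errors mean cross-object disagreement.

osa_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "osadetect_error"), call = call))
}

abort_io          <- function(msg) osa_abort(msg, "osadetect_io_error")
abort_format      <- function(msg) osa_abort(msg, "osadetect_format_error")
abort_param       <- function(msg) osa_abort(msg, "osadetect_param_error")
abort_consistency <- function(msg) osa_abort(msg, "osadetect_consistency_error")
abort_degenerate  <- function(msg) osa_abort(msg, "osadetect_degenerate_error")
abort_state       <- function(msg) osa_abort(msg, "osadetect_state_error")
abort_leakage     <- function(msg) osa_abort(msg, "osadetect_leakage_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a child seed from a top-level seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
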