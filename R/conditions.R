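# Classed error conditions so callers (and tests) can distinguish failure
# modes without string matching.

fp_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fpscreen_error")))
}

abort_format <- function(msg) fp_abort(msg, "fpscreen_format_error")
abort_integrity <- function(msg) fp_abort(msg, "fpscreen_integrity_error")
abort_value <- function(msg) fp_abort(msg, "fpscreen_value_error")
abort_controls <- function(msg) fp_abort(msg, "fpscreen_insufficient_controls_error")
abort_replicates <- function(msg) fp_abort(msg, "fpscreen_insufficient_replicates_error")
abort_degenerate <- function(msg) fp_abort(msg, "fpscreen_degenerate_error")
abort_fit <- function(msg) fp_abort(msg, "fpscreen_fit_error")
abort_grid <- function(msg) fp_abort(msg, "fpscreen_grid_error")
abort_baseline <- function(msg) fp_abort(msg, "fpscreen_missing_baseline_error")
abort_config <- function(msg) fp_abort(msg, "fpscreen_config_error")
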