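# Classed conditions so callers (and the CLI) can distinguish bad input
# from failures of the computation itself.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("chnri_validation_error", "chnri_error")))
}

stop_computation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("chnri_computation_error", "chnri_error")))
}
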