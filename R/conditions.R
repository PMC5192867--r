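# Classed conditions so callers can distinguish contract violations
# programmatically (tryCatch(ibmsens_duplicate_factor = ...)).

abort_ibmsens <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("ibmsens_", class), "ibmsens_error")))
}

#' @keywords internal
"_PACKAGE"
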