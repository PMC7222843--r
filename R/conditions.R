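# Classed conditions so callers can distinguish failure modes programmatically.
# Every error carries class c("slurrycbc_error_<kind>", "slurrycbc_error", "error").

stop_slurrycbc <- function(kind, msg, ..., call. = FALSE) {
  cond <- errorCondition(
    sprintf(msg, ...),
    class = c(paste0("slurrycbc_error_", kind), "slurrycbc_error")
  )
  stop(cond)
}

warn_slurrycbc <- function(kind, msg, ...) {
  cond <- warningCondition(
    sprintf(msg, ...),
    class = c(paste0("slurrycbc_warning_", kind), "slurrycbc_warning")
  )
  warning(cond)
}
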