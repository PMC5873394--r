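# Classed conditions so callers can distinguish failure modes programmatically.
# All errors carry the class "hgtclock_error" plus a specific subclass.

abort_hgt <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "hgtclock_error")))
}

warn_hgt <- function(message, class, ...) {
  warning(warningCondition(message, ..., class = c(class, "hgtclock_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
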