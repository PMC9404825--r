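# Classed error helpers so callers can condition on failure modes.

fq_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fibroquant_error")))
}

fq_assert <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) fq_stop(class, fmt, ...)
  invisible(TRUE)
}
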