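# Classed conditions so callers can distinguish failure modes programmatically.

kc_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "kidclass_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

kc_warn <- function(message, class = "kidclass_warning") {
  warning(structure(
    class = c(class, "kidclass_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
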