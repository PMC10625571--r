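# Classed error conditions so callers can branch on failure modes
# programmatically instead of matching message strings.

nf_stop <- function(class, msg, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("nariform_", class), "nariform_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
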