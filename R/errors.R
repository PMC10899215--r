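# Classed conditions so callers can distinguish structural problems
# (cycles, unknown nodes) from numerical ones (rank deficiency, empty
# Monte-Carlo windows).

qaop_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "qaop_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}
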