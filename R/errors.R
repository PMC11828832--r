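# Classed conditions so callers (and the CLI) can react to specific
# failure modes without string-matching messages.

cm_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "chatmetrics_error"),
                      call = call))
}

cm_warn <- function(msg, class = "chatmetrics_warning") {
  warning(warningCondition(msg, class = c(class, "chatmetrics_warning")))
}
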