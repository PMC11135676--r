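## Classed error conditions so callers/tests can discriminate failure modes.

pk_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pulchkin_error"),
                      call = call))
}

pk_assert <- function(ok, msg, class = "invalid_input") {
  if (!isTRUE(ok)) pk_stop(msg, class, call = sys.call(-1))
  invisible(TRUE)
}
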