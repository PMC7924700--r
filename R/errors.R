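#' @keywords internal
tcob_abort <- function(class, msg, data = list()) {
  cond <- structure(
    class = c(class, "tcob_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
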