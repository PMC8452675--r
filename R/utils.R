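# internal helpers

stop_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
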