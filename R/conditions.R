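# Classed conditions so callers (and the CLI) can distinguish bad input
# (validation), missing lookups, and optimizer failures (convergence).

pg_stop <- function(msg, class = "pg_error_validation", call. = FALSE) {
  stop(structure(
    class = c(class, "pg_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

pg_assert <- function(cond, msg, class = "pg_error_validation") {
  if (!isTRUE(cond)) pg_stop(msg, class)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
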