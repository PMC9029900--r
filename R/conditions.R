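# Structured error conditions. Every error raised by the package carries the
# class "vancnomo_error" plus a specific subclass so callers (notably the CLI)
# can map failures to exit codes without parsing messages.

stop_vanc <- function(subclass, message, ...) {
  cond <- structure(
    class = c(subclass, "vancnomo_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

stop_validation <- function(message, ...) {
  stop_vanc("vancnomo_validation_error", message, ...)
}

stop_out_of_range <- function(message, ...) {
  stop_vanc("vancnomo_out_of_range", message, ...)
}

stop_missing_age <- function(message, ...) {
  stop_vanc("vancnomo_missing_age", message, ...)
}

stop_schema <- function(message, ...) {
  stop_vanc("vancnomo_schema_error", message, ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
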