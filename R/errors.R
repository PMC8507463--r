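# Structured condition classes. Every engine error is a subclass of
# "obsdex_error" so callers can catch the family or a specific kind.

obsdex_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "obsdex_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

config_error      <- function(msg, ...) obsdex_abort("obsdex_config_error", msg, ...)
database_error    <- function(msg, ...) obsdex_abort("obsdex_database_error", msg, ...)
assignment_error  <- function(msg, ...) obsdex_abort("obsdex_assignment_error", msg, ...)
units_error       <- function(msg, ...) obsdex_abort("obsdex_units_error", msg, ...)
measurement_error <- function(msg, ...) obsdex_abort("obsdex_measurement_error", msg, ...)
permission_error  <- function(msg, ...) obsdex_abort("obsdex_permission_error", msg, ...)
navigation_error  <- function(msg, ...) obsdex_abort("obsdex_navigation_error", msg, ...)
session_error     <- function(msg, ...) obsdex_abort("obsdex_session_error", msg, ...)
incomplete_error  <- function(msg, ...) obsdex_abort("obsdex_incomplete_error", msg, ...)
log_parse_error   <- function(msg, ...) obsdex_abort("obsdex_parse_error", msg, ...)
spec_error        <- function(msg, ...) obsdex_abort("obsdex_spec_error", msg, ...)
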