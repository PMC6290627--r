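# Structured error conditions. Every user-facing failure carries a subclass of
# "teamdyn_error" so callers (and the CLI) can map failures to exit codes
# without parsing messages.

td_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "teamdyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_format     <- function(msg, ...) td_abort(msg, "teamdyn_format_error", ...)
abort_validation <- function(msg, ...) td_abort(msg, "teamdyn_validation_error", ...)
abort_empty      <- function(msg, ...) td_abort(msg, "teamdyn_empty_selection_error", ...)
abort_domain     <- function(msg, ...) td_abort(msg, "teamdyn_domain_error", ...)
abort_group_size <- function(msg, ...) td_abort(msg, "teamdyn_group_size_error", ...)
abort_degenerate <- function(msg, ...) td_abort(msg, "teamdyn_degenerate_signal_error", ...)
abort_config     <- function(msg, ...) td_abort(msg, "teamdyn_config_error", ...)
abort_data       <- function(msg, ...) td_abort(msg, "teamdyn_insufficient_data_error", ...)
abort_io         <- function(msg, ...) td_abort(msg, "teamdyn_io_error", ...)
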