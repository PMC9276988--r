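# Structured conditions: every error raised by the package carries class
# "spsp_error" plus a specific subclass so callers (and the CLI exit-code
# mapping) can dispatch on failure kind rather than on message text.

spsp_stop <- function(message, class, call = sys.call(-1), ...) {
  cnd <- structure(
    class = c(class, "spsp_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}

# usage / configuration problems -> CLI exit code 2
stop_config <- function(message, ...) spsp_stop(message, "spsp_config_error", ...)

# data / protocol problems -> CLI exit code 3
stop_domain      <- function(message, ...) spsp_stop(message, "spsp_domain_error", ...)
stop_format      <- function(message, ...) spsp_stop(message, c("spsp_format_error", "spsp_domain_error"), ...)
stop_parse       <- function(message, ...) spsp_stop(message, c("spsp_parse_error", "spsp_domain_error"), ...)
stop_consistency <- function(message, ...) spsp_stop(message, c("spsp_consistency_error", "spsp_domain_error"), ...)
stop_io          <- function(message, ...) spsp_stop(message, c("spsp_io_error", "spsp_domain_error"), ...)
stop_manifest    <- function(message, ...) spsp_stop(message, c("spsp_manifest_error", "spsp_domain_error"), ...)
stop_degenerate  <- function(message, ...) spsp_stop(message, c("spsp_degenerate_error", "spsp_domain_error"), ...)
stop_not_converged <- function(message, ...) spsp_stop(message, c("spsp_not_converged_error", "spsp_domain_error"), ...)
stop_protocol    <- function(message, ...) spsp_stop(message, c("spsp_protocol_error", "spsp_domain_error"), ...)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
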