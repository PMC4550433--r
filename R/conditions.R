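# Classed conditions so callers can distinguish bad parameters
# (config), bad values (data) and malformed files (format).

pg_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "pathgsea_error")))
}

stop_config <- function(msg, ...) pg_stop("pathgsea_config_error", msg, ...)
stop_data   <- function(msg, ...) pg_stop("pathgsea_data_error", msg, ...)
stop_format <- function(msg, ...) pg_stop("pathgsea_format_error", msg, ...)
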