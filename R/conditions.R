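# Condition constructors shared across the package.  Three error classes map
# onto the pipeline's exit codes: configuration (2), data (3), fitting (4).

ant_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ant_config_error <- function(msg, ...) ant_error("ant_config_error", msg, ...)
ant_data_error   <- function(msg, ...) ant_error("ant_data_error", msg, ...)
ant_fit_error    <- function(msg, ...) ant_error("ant_fit_error", msg, ...)

stopifnot_config <- function(cond, msg) if (!isTRUE(cond)) ant_config_error(msg)
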