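## Typed conditions so callers (and the CLI) can map failures to exit codes.

stopUsage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mirtf_usage_error", "mirtf_error")))
}

stopFormat <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mirtf_format_error", "mirtf_error")))
}

stopData <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mirtf_data_error", "mirtf_error")))
}

stopIO <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mirtf_io_error", "mirtf_error")))
}
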