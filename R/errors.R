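# Condition helpers. Three error classes map onto the CLI exit codes:
# validation (2), I/O (3), statistical precondition (4).

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("seqfrust_validation_error", "seqfrust_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("seqfrust_io_error", "seqfrust_error")))
}

stop_stat <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("seqfrust_stat_error", "seqfrust_error")))
}
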