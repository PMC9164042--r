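# Condition helpers: every user-facing failure is classed so callers (and the
# command-line driver) can map validation vs format vs structural vs I/O
# failures onto distinct exit codes.

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "scladder_format_error")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "scladder_validation_error")
}

stop_structural <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "scladder_structural_error")
}

stop_io <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "scladder_io_error")
}
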