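# structured conditions shared across modules

.formatError <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("pemscreen_format_error", "error"),
                      call = call))
}

.configError <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("pemscreen_config_error", "error"),
                      call = call))
}

.insufficientData <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c("pemscreen_insufficient_data", "error"),
                      call = call))
}

# edge membership: outermost two rows/columns of a rows x cols grid
.isEdge <- function(row, col, rows, cols) {
  row <= 2L | row > rows - 2L | col <= 2L | col > cols - 2L
}
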