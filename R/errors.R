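# Condition classes used across the package:
#   cm_input_error  -- caller passed invalid arguments / data
#   cm_format_error -- a file violated its format contract
#   cm_config_error -- pipeline configuration invalid (CLI exit code 2)
#   cm_stage_error  -- a pipeline stage failed (CLI exit code 3)

.cmStop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c(class, "cladeMotifsError")))
}

stopInput  <- function(fmt, ...) .cmStop("cm_input_error", fmt, ...)
stopFormat <- function(fmt, ...) .cmStop("cm_format_error", fmt, ...)
stopConfig <- function(fmt, ...) .cmStop("cm_config_error", fmt, ...)
stopStage  <- function(fmt, ...) .cmStop("cm_stage_error", fmt, ...)
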