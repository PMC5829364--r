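# Classed conditions so callers (and the CLI) can distinguish bad input
# files (format), bad values (validation), and bad arguments (usage).

np_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "netpharm_error")))
}

np_format_error <- function(msg) np_stop(msg, "netpharm_format_error")
np_validation_error <- function(msg) np_stop(msg, "netpharm_validation_error")
np_usage_error <- function(msg) np_stop(msg, "netpharm_usage_error")

np_log <- function(..., quiet = getOption("netpharm.quiet", FALSE)) {
  if (!isTRUE(quiet)) message("[netpharm] ", ...)
  invisible(NULL)
}
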