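# Condition classes used across the package.  `parse` and `schema` cover
# malformed or out-of-dialect program documents, `validation` covers
# cross-reference and probability failures, `runtime` covers failures
# during simulation (e.g. an updater returning invalid probabilities).
# The command-line wrapper maps parse/schema/validation to exit code 1
# and runtime errors to exit code 2.

stop_stg <- function(class = c("validation", "parse", "schema", "runtime"),
                     msg, ...) {
  class <- match.arg(class)
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(paste0("stg_", class, "_error"), "stg_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
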