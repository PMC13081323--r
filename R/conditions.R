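# Classed conditions so callers (and the CLI) can map failures to categories.

lw_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lungwater_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

lw_validation_error <- function(msg, ...) lw_error("lungwater_validation_error", msg, ...)
lw_alignment_error  <- function(msg, ...) lw_error("lungwater_alignment_error", msg, ...)
lw_format_error     <- function(msg, ...) lw_error("lungwater_format_error", msg, ...)
lw_usage_error      <- function(msg, ...) lw_error("lungwater_usage_error", msg, ...)
lw_numeric_error    <- function(msg, ...) lw_error("lungwater_numeric_error", msg, ...)

#' Exit-code class of a lungwater condition
#'
#' Maps a caught condition to the exit code the command-line interface uses:
#' 64 usage, 65 format, 66 validation (including alignment), 70 numeric or
#' any other package error, 1 for foreign errors.
#'
#' @param cond a condition object.
#' @return integer exit code.
#' @keywords internal
lw_exit_code <- function(cond) {
  if (inherits(cond, "lungwater_usage_error")) return(64L)
  if (inherits(cond, "lungwater_format_error")) return(65L)
  if (inherits(cond, "lungwater_validation_error") ||
      inherits(cond, "lungwater_alignment_error")) return(66L)
  if (inherits(cond, "lungwater_error")) return(70L)
  1L
}
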