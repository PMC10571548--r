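# Structured conditions so callers (and the CLI) can map failures to exit
# codes without string matching.

pt_stop <- function(subclass, msg) {
  cond <- structure(
    class = c(subclass, "pentrack_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  )
  stop(cond)
}

pt_parse_error      <- function(msg) pt_stop("pentrack_parse_error", msg)
pt_validation_error <- function(msg) pt_stop("pentrack_validation_error", msg)
pt_evaluation_error <- function(msg) pt_stop("pentrack_evaluation_error", msg)
pt_config_error     <- function(msg) pt_stop("pentrack_config_error", msg)
pt_missing_input    <- function(msg) pt_stop("pentrack_missing_input", msg)

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    pt_validation_error(sprintf("'%s' must be a single finite number", name))
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper)
    pt_validation_error(sprintf("'%s' = %g is out of range", name, x))
  invisible(x)
}
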