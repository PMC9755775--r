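# Structured error conditions shared across the package.
#
# Four classes are used throughout and mapped to distinct exit codes by the
# command-line wrapper:
#   vialroute_validation_error -- bad argument values (exit 2)
#   vialroute_limit_error      -- configured caps exceeded (exit 2)
#   vialroute_format_error     -- unparseable input files (exit 3)
#   vialroute_io_error         -- filesystem failures (exit 3)

vr_stop <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "vialroute_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg, ...) vr_stop("vialroute_validation_error", msg, ...)
stop_limit      <- function(msg, ...) vr_stop("vialroute_limit_error", msg, ...)
stop_format     <- function(msg, ...) vr_stop("vialroute_format_error", msg, ...)
stop_io         <- function(msg, ...) vr_stop("vialroute_io_error", msg, ...)

# scalar checks used by constructors
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_validation("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  x
}

check_count <- function(x, name, lower = 1L) {
  x <- check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_validation("'%s' must be an integer", name)
  as.integer(x)
}
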