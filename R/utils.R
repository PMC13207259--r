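#' @importFrom stats qnorm rbinom rnorm rpois runif rexp setNames
#' @importFrom utils head
NULL

.datatable.aware <- TRUE

# Classed conditions so callers/tests can distinguish failure modes.
ted_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tedclaims_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_config <- function(msg, ...) ted_stop("tedclaims_config_error", msg, ...)
stop_input <- function(msg, ...) ted_stop("tedclaims_input_error", msg, ...)
stop_infeasible <- function(msg, ...) ted_stop("tedclaims_infeasible_error", msg, ...)
stop_leakage <- function(msg, ...) ted_stop("tedclaims_leakage_error", msg, ...)
stop_stage <- function(stage, cause) {
  ted_stop("tedclaims_stage_error", "stage '%s' failed: %s", stage, conditionMessage(cause))
}

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

#' Convert calendar dates to integer day offsets
#'
#' Dates are held internally as integer days since 1970-01-01 so that
#' window arithmetic (lookback spans, co-occurrence gaps) is exact;
#' calendar rendering happens only at I/O boundaries.
#'
#' @param x a `Date`, ISO-8601 character vector, or integer day offset.
#' @return integer vector of day offsets.
#' @export
as_day <- function(x) {
  if (inherits(x, "Date")) return(as.integer(unclass(x)))
  if (is.character(x)) return(as.integer(unclass(as.Date(x))))
  if (is.numeric(x)) return(as.integer(x))
  stop_input("cannot interpret object of class '%s' as a date", class(x)[1])
}

#' @rdname as_day
#' @export
day_as_date <- function(x) as.Date(as.integer(x), origin = "1970-01-01")

# Stable per-stage seed derivation: one top-level seed fans out to stage
# seeds by hashing the stage name, keeping results < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
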