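# Condition helpers: every user-facing failure carries a class so callers and
# tests can discriminate domain errors (bad values) from validation errors
# (inconsistent structures) and schema errors (malformed files).

ab_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "airburden_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_domain <- function(msg) ab_stop(msg, "airburden_domain_error")
stop_validation <- function(msg) ab_stop(msg, "airburden_validation_error")
stop_schema <- function(msg) ab_stop(msg, "airburden_schema_error")
stop_config <- function(msg) ab_stop(msg, "airburden_config_error")
stop_type <- function(msg) ab_stop(msg, "airburden_type_error")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Round half up to a fixed number of decimals
#'
#' Reporting-layer rounding used when comparing computed quantities with
#' values printed to a fixed precision (Lancet-style half-up rounding, as
#' opposed to R's banker's rounding in [round()]).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.5)       # 1, where round(0.5) gives 0
#' round_half_up(17.75, 1)  # 17.8
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
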