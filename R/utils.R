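#' Round half-up
#'
#' Rounds away from zero on exact halves (so 29.5 lbs becomes 30, not the
#' round-to-even 30/28 ambiguity of [base::round()]). Used for whole-pound
#' honey yields and for currency carried in integer cents, where printed
#' dollar figures must not drift with binary-float representation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(48.085, 0) # 48
#' round_half_up(29.5, 0)   # 30
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  scale <- 10^digits
  # add a one-ulp nudge so values like 0.5 that sit a hair below the exact
  # half after scaling still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# dollars -> integer cents, half-up; keeps all currency arithmetic exact
to_cents <- function(dollars) {
  as.integer(round_half_up(dollars * 100))
}

from_cents <- function(cents) {
  cents / 100
}

abort_config <- function(field, msg) {
  rlang::abort(
    sprintf("invalid configuration: field '%s' %s", field, msg),
    class = "beecotox_config_error"
  )
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "beecotox_validation_error")
}
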