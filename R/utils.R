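#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the "half-up" convention
#' used in clinical reporting), unlike [base::round()] which rounds half to
#' even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(0.8145, 3)
#' round_half_up(2.5, 0)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale * sign(x)
}

stop_domain <- function(msg, ...) {
  abort(msg, class = c("psc_domain_error", "psc_error"), ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = c("psc_validation_error", "psc_error"), ...)
}

stop_schema <- function(msg, ...) {
  abort(msg, class = c("psc_schema_error", "psc_error"), ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
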