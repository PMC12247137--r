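#' Round half away from zero
#'
#' Fixed-precision rounding with ties moved away from zero, the convention used
#' for all reported percentages (base [round()] rounds half to even, which
#' turns 37.35 into 37.3 rather than the conventional 37.4).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(37.35, -37.35, 198 / 530 * 100), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared input checks ---------------------------------------------------------

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s.",
                  name, if (strict) ">" else ">=", format(min)),
          class = "drgmodal_config_error")
  }
  invisible(x)
}

data_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "drgmodal_data_error")
}

config_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "drgmodal_config_error")
}
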