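#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used throughout the reporting layer (base [round()] rounds
#' half to even). A half tie at the last kept digit always moves outward,
#' so 0.205 prints as 0.21 and -0.205 as -0.21.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_away(0.205, 2) # 0.21
#' round_half_away(2.5, 0)   # 3
#' @export
round_half_away <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 0)
  scale <- 10^digits
  # pre-round at 9 decimals so a mathematical tie (e.g. 0.205) is not
  # pushed below the half point by double representation error
  sign(x) * floor(round(abs(x) * scale, 9) + 0.5) / scale
}

#' Clamp values into an interval
#'
#' @param x Numeric vector.
#' @param lo,hi Interval bounds.
#' @return `x` with values below `lo` set to `lo` and above `hi` set to `hi`.
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Serialize floats at 6 significant digits for TSV interchange.
format_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, 6), format = "g", digits = 6))
}
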