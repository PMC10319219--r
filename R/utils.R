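#' Integer percentage share, rounded half away from zero
#'
#' The rounding convention behind printed shares such as "29%": 28.5 rounds
#' to 29, not to the even neighbor.
#'
#' @param part,whole Numerator and denominator (same units).
#' @return Integer percent.
#' @export
share_percent <- function(part, whole) {
  if (whole == 0) stop("share of an empty total is undefined", call. = FALSE)
  x <- 100 * part / whole
  sign(x) * floor(abs(x) + 0.5)
}

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
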