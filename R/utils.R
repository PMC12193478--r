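## Small shared helpers.

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching the printed
#' style of reported percentages and coefficients (e.g. -0.955 renders as
#' -0.96, 47.36\% as 47.4\%), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half away from zero
#' @examples
#' roundHalfUp(c(0.125, -0.955, 47.368), c(2, 2, 1))
#' @export
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  # nudge by one ulp so values printed as exact halves (stored minutely
  # below .5 in binary) still round away from zero
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Significance stars from p-values
#'
#' @param p numeric vector of p-values (typically FDR-adjusted)
#' @return character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `""` otherwise (and for `NA`)
#' @examples
#' significanceStars(c(0.0005, 0.004, 0.04, 0.2, NA))
#' @export
significanceStars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05]  <- "*"
  out[!is.na(p) & p < 0.01]  <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

## Format a coefficient to two decimals, half away from zero; NA -> blank.
formatCoef <- function(x) {
  ifelse(is.na(x), "", sprintf("%.2f", roundHalfUp(x, 2L)))
}

## stopifnot-style validation with field naming, for config constructors
assertField <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}
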