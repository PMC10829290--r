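# dB <-> linear conversions used throughout fisheries acoustics.
# Sv (dB re 1 m-1) is always averaged in the linear domain, never in dB.

#' Convert between decibel and linear backscatter
#'
#' `db_to_linear()` maps Sv (dB re 1 m^-1) or TS (dB re 1 m^2) to the linear
#' coefficient (`10^(x/10)`); `linear_to_db()` is the inverse. A linear value
#' of 0 maps to `-Inf` dB, the conventional below-detection sentinel.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' linear_to_db(db_to_linear(-70))
#' @export
db_to_linear <- function(x) 10^(x / 10)

#' @rdname db_to_linear
#' @export
linear_to_db <- function(x) {
  out <- rep(-Inf, length(x))
  pos <- !is.na(x) & x > 0
  out[pos] <- 10 * log10(x[pos])
  out[is.na(x)] <- NA_real_
  out
}

# 4*pi*1852^2: conversion from depth-integrated sv (m^-1 * m) to NASC
# (m^2 nmi^-2), per the standard echo-integration definitions.
nasc_constant <- function() 4 * pi * 1852^2

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be a positive finite number.", name))
  }
  invisible(x)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

# Half-open binning [b, b+1) used for depth (1 m) and temperature (1 degC).
bin_lower <- function(x, width = 1, origin = 0) {
  origin + floor((x - origin) / width) * width
}
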