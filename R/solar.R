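#' Solar elevation angle
#'
#' Elevation of the sun above the horizon (degrees) at a given time and
#' geographic position, from the standard low-precision solar ephemeris
#' (fractional-year formulation of declination and the equation of time).
#' Accuracy is a fraction of a degree, ample for splitting a biologging
#' record into day and night.
#'
#' @param time POSIXct (UTC).
#' @param lon,lat Longitude and latitude (decimal degrees, east/north
#'   positive).
#' @return Numeric vector of elevations (degrees).
#' @examples
#' solar_elevation(as.POSIXct("2018-05-19 04:00:00", tz = "UTC"),
#'                 lon = 113.68, lat = -22.72)
#' @export
solar_elevation <- function(time, lon, lat) {
  tt <- as.POSIXlt(time, tz = "UTC")
  doy <- tt$yday + 1
  hour <- tt$hour + tt$min / 60 + tt$sec / 3600
  gamma <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)  # fractional year (rad)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
                        0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  tst <- hour * 60 + eqtime + 4 * lon            # true solar time (min)
  ha <- (tst / 4 - 180) * pi / 180               # hour angle (rad)
  lat_r <- lat * pi / 180
  cos_zen <- sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(ha)
  90 - acos(pmin(pmax(cos_zen, -1), 1)) * 180 / pi
}
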