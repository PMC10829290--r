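#' Reconstruct a continuous pseudo-track from sparse fixes
#'
#' Interpolates easting and northing against time with a natural cubic
#' spline through the attached position fixes, evaluated at every 1-Hz
#' record timestamp inside the fix time-span, and pairs each interpolated
#' position with the measured depth. The spline passes exactly through
#' every fix; with exactly two fixes it degenerates to a straight
#' constant-speed path. Record samples outside the fix span are dropped
#' rather than extrapolated.
#'
#' @param fixes Fix tibble (`time`, `x`, `y`, optionally `attached`; only
#'   attached fixes are used). At least 2 fixes with distinct times.
#' @param record 1-Hz tag record (`time`, `depth_m`, optionally
#'   `shark_id`).
#' @return A `pseudo_track` tibble: `shark_id`, `time`, `x`, `y`,
#'   `depth_m`.
#' @examples
#' t0 <- as.POSIXct("2018-05-19 02:00:00", tz = "UTC")
#' fx <- tibble::tibble(time = t0 + c(0, 600, 1200), x = c(0, 400, 500),
#'                      y = c(0, 100, 600))
#' rec <- tibble::tibble(time = t0 + 0:1200, depth_m = 5)
#' trk <- interpolate_track(fx, rec)
#' trk[trk$time %in% fx$time, ]
#' @export
interpolate_track <- function(fixes, record) {
  if ("attached" %in% names(fixes)) {
    fixes <- dplyr::filter(fixes, .data$attached)
  }
  fixes <- dplyr::arrange(fixes, .data$time)
  ft <- as.numeric(fixes$time)
  if (anyDuplicated(ft)) {
    fixes <- fixes[!duplicated(ft), ]
    ft <- as.numeric(fixes$time)
  }
  if (nrow(fixes) < 2) abort("Insufficient fixes: need >= 2 with distinct times.")
  if (is.unsorted(ft, strictly = TRUE)) abort("Fix times must be strictly increasing.")

  rt <- as.numeric(record$time)
  inside <- rt >= ft[1] & rt <= ft[length(ft)]
  if (!any(inside)) abort("Record does not overlap the fix time-span.")

  sx <- splinefun(ft, fixes$x, method = "natural")
  sy <- splinefun(ft, fixes$y, method = "natural")
  id <- if ("shark_id" %in% names(record)) record$shark_id[inside][1] else {
    if ("shark_id" %in% names(fixes)) fixes$shark_id[1] else NA_character_
  }
  out <- tibble::tibble(
    shark_id = id,
    time = record$time[inside],
    x = sx(rt[inside]),
    y = sy(rt[inside]),
    depth_m = record$depth_m[inside]
  )
  structure(out, class = c("pseudo_track", class(tibble::tibble())))
}
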