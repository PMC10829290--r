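#' Flag floating-tag fixes by their programmed acquisition cadence
#'
#' A recovered tag that has released from the animal floats at the surface
#' and acquires positions exactly on its programmed schedule, whereas an
#' attached tag transmits opportunistically whenever the antenna clears the
#' water. The filter therefore marks as detached the trailing maximal run
#' of at least `run_len` fixes whose consecutive time gaps equal the
#' programmed interval (within `tolerance`); every fix from the start of
#' that run onward is excluded from the attached track.
#'
#' @param fixes Tibble of time-sorted fixes (`time` POSIXct plus any other
#'   columns).
#' @param interval Programmed acquisition interval (s; default 30 min).
#' @param run_len Minimum number of regularly spaced fixes that counts as
#'   evidence of detachment.
#' @param tolerance Allowed deviation of a gap from `interval` (s).
#' @return The input with a logical `attached` column; detached fixes keep
#'   their rows but are flagged `FALSE`.
#' @examples
#' t0 <- as.POSIXct("2018-05-19 00:00:00", tz = "UTC")
#' fx <- tibble::tibble(time = t0 + c(0, 700, 2500, 5000, 6800,
#'                                    8000 + 1800 * (0:5)))
#' filter_detached(fx)
#' @export
filter_detached <- function(fixes, interval = 1800, run_len = 3,
                            tolerance = 120) {
  if (nrow(fixes) == 0) {
    fixes$attached <- logical(0)
    return(fixes)
  }
  if (is.unsorted(fixes$time)) abort("`fixes` must be time-sorted.")
  n <- nrow(fixes)
  attached <- rep(TRUE, n)
  if (n >= run_len) {
    gaps <- as.numeric(diff(fixes$time), units = "secs")
    regular <- abs(gaps - interval) <= tolerance
    # length of the trailing run of regular gaps
    run <- 0
    for (g in rev(regular)) {
      if (!g) break
      run <- run + 1
    }
    if (run + 1 >= run_len) {
      attached[(n - run):n] <- FALSE
    }
  }
  fixes$attached <- attached
  fixes
}
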