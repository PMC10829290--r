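#' Echo-integrate a cleaned ping set onto along-track x depth cells
#'
#' Averages the linear volume backscattering coefficient
#' `sv = 10^(Sv/10)` over unflagged samples in cells of `interval_s`
#' seconds along track by `bin_m` metres of depth, and reports the
#' mean volume backscattering strength `MVBS = 10 log10(mean sv)` per
#' cell. Averaging is always done in the linear domain. Below-detection
#' samples enter the mean as linear 0, so a cell of only below-detection
#' samples gets the `-Inf` MVBS sentinel (density 0 downstream); samples
#' flagged `surface`, `seabed` or `trawl` are excluded entirely.
#'
#' @param pings A cleaned `ping_set` (see [clean_echogram()]).
#' @param interval_s Along-track integration interval (s); the survey speed
#'   makes the default 30 s roughly 150 m of transect line.
#' @param bin_m Vertical bin size (m).
#' @return A `gridded_sv` tibble: `interval`, `depth_bin` (lower edge, m),
#'   `mvbs_db`, `n_samples`, cell centroid `x`, `y` and mid-time `time`.
#' @examples
#' cfg <- sim_config(noise_sd_db = 0, seed = 5)
#' grid <- simulate_survey(simulate_scene(cfg), cfg) |>
#'   clean_echogram() |>
#'   echo_integrate()
#' head(grid)
#' @export
echo_integrate <- function(pings, interval_s = 30, bin_m = 1) {
  if (nrow(pings) == 0) abort("`pings` is empty.")
  assert_positive(interval_s, "interval_s")
  assert_positive(bin_m, "bin_m")

  t0 <- min(pings$time)
  kept <- pings |>
    dplyr::filter(.data$flag %in% c("ok", "below_detection")) |>
    dplyr::mutate(
      interval = floor(as.numeric(difftime(.data$time, t0, units = "secs")) /
                         interval_s),
      depth_bin = bin_lower(.data$depth, bin_m),
      sv_lin = dplyr::if_else(.data$flag == "below_detection",
                              0, db_to_linear(.data$sv_db))
    )
  out <- kept |>
    dplyr::group_by(.data$interval, .data$depth_bin) |>
    dplyr::summarise(
      mvbs_db = linear_to_db(mean(.data$sv_lin)),
      n_samples = dplyr::n(),
      x = mean(.data$x), y = mean(.data$y),
      time = mean(.data$time),
      .groups = "drop"
    )
  structure(out, class = c("gridded_sv", class(tibble::tibble())),
            bin_m = bin_m, interval_s = interval_s)
}

#' Nautical area scattering coefficient per along-track interval
#'
#' Integrates the linear backscattering coefficient over a depth layer and
#' scales to the nautical area scattering coefficient
#' `NASC = 4 pi 1852^2 * sum(sv * dz)` (m^2 nmi^-2), the standard areal
#' biomass proxy, averaged over the pings falling in each along-track
#' interval (default 500 m of survey line, approximated by survey time at
#' the configured speed). Below-detection cells contribute 0; intervals
#' with no valid cells get `NA`.
#'
#' @param grid A `gridded_sv` from [echo_integrate()].
#' @param interval_m Along-track interval length (m).
#' @param depth_range Two-element numeric `[min, max)` depth layer (m);
#'   `Inf` extends to the seabed.
#' @param speed_ms Nominal survey speed used to convert the time-indexed
#'   integration intervals to distance.
#' @return A `nasc_profile` tibble: `interval_500`, `nasc` (m^2 nmi^-2),
#'   centroid `x`, `y`, and `n_cells`.
#' @examples
#' cfg <- sim_config(noise_sd_db = 0, seed = 5)
#' nasc <- simulate_survey(simulate_scene(cfg), cfg) |>
#'   clean_echogram() |>
#'   echo_integrate() |>
#'   compute_nasc()
#' head(nasc)
#' @export
compute_nasc <- function(grid, interval_m = 500, depth_range = c(5, Inf),
                         speed_ms = 5.144) {
  if (nrow(grid) == 0) abort("`grid` is empty.")
  bin_m <- attr(grid, "bin_m") %||% 1
  interval_s <- attr(grid, "interval_s") %||% 30
  cells_per_interval <- max(1, round(interval_m / (speed_ms * interval_s)))

  layer <- grid |>
    dplyr::filter(.data$depth_bin >= depth_range[1],
                  .data$depth_bin + bin_m <= depth_range[2] |
                    is.infinite(depth_range[2]))
  if (nrow(layer) == 0) {
    return(structure(
      tibble::tibble(interval_500 = integer(0), nasc = numeric(0),
                     x = numeric(0), y = numeric(0), n_cells = integer(0)),
      class = c("nasc_profile", class(tibble::tibble()))
    ))
  }
  out <- layer |>
    dplyr::mutate(interval_500 = .data$interval %/% cells_per_interval,
                  sv_lin = db_to_linear(.data$mvbs_db)) |>
    dplyr::group_by(.data$interval_500) |>
    dplyr::summarise(
      # per-ping-interval depth integral, then mean across those intervals
      nasc = nasc_constant() * bin_m *
        sum(.data$sv_lin) / dplyr::n_distinct(.data$interval),
      x = mean(.data$x), y = mean(.data$y),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
  structure(out, class = c("nasc_profile", class(tibble::tibble())))
}

#' Scale gridded backscatter to volumetric prey density
#'
#' Converts MVBS to volumetric density `n = sv / sigma_bs =
#' 10^(MVBS/10) / 10^(TS/10)` (individuals m^-3) using the
#' population-average single-animal target strength. Below-detection cells
#' (`-Inf` MVBS) map to density 0; cells absent from the grid stay missing.
#'
#' @param grid A `gridded_sv` from [echo_integrate()].
#' @param ts A `ts_result` from [dwba_target_strength()] or a single TS
#'   value (dB re 1 m^2).
#' @return A `density_grid` tibble with the cell indexing of `grid` plus
#'   `density` (ind m^-3).
#' @examples
#' cfg <- sim_config(noise_sd_db = 0, seed = 5)
#' dens <- simulate_survey(simulate_scene(cfg), cfg) |>
#'   clean_echogram() |>
#'   echo_integrate() |>
#'   sv_to_density(ts = -88.53)
#' head(dens)
#' @export
sv_to_density <- function(grid, ts) {
  ts_db <- if (inherits(ts, "ts_result")) ts$ts_db else as.numeric(ts)
  if (!is.finite(ts_db)) abort("TS is not finite; cannot scale Sv to density.")
  out <- grid |>
    dplyr::mutate(density = dplyr::if_else(
      is.finite(.data$mvbs_db),
      db_to_linear(.data$mvbs_db) / db_to_linear(ts_db),
      0
    ))
  structure(out, class = c("density_grid", class(tibble::tibble())),
            bin_m = attr(grid, "bin_m") %||% 1, ts_db = ts_db)
}
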