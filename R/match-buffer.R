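#' Extract mean prey-density depth profiles around predator locations
#'
#' For each shark location, finds the surveyed density cells whose
#' centroid lies strictly within the horizontal buffer radius (a vertical
#' cylinder through the water column) and whose survey time is within the
#' temporal matching window, and averages density per 1-m depth bin over
#' those cells — zeros (below-detection) included, trawl-excluded cells
#' never. Locations with no in-buffer cells are dropped and counted.
#'
#' @param track Tibble of shark locations: `time`, `x`, `y`, optionally
#'   `shark_id`. Typically sparse fixes or a thinned pseudo-track.
#' @param density A `density_grid` from [sv_to_density()] (columns `time`,
#'   `x`, `y`, `depth_bin`, `density`).
#' @param radius Buffer radius (m); distance must be strictly less.
#' @param time_window Temporal matching half-window (s; default 6 h).
#' @return A tibble of class `matched_profile`: `shark_id`, `point_id`,
#'   `time`, `x`, `y`, `depth_bin`, `mean_density`, `n_cells`. The number
#'   of unmatched locations is in attribute `n_unmatched`.
#' @examples
#' cfg <- sim_config(noise_sd_db = 0, seed = 6, track_duration_s = 1200)
#' sc <- simulate_scene(cfg)
#' dens <- simulate_survey(sc, cfg) |>
#'   clean_echogram() |>
#'   echo_integrate() |>
#'   sv_to_density(ts = cfg$ts_db)
#' sh <- simulate_shark(sc, cfg)
#' prof <- match_buffer(sh$fixes, dens)
#' head(prof)
#' @export
match_buffer <- function(track, density, radius = 1000, time_window = 6 * 3600) {
  assert_positive(radius, "radius")
  assert_positive(time_window, "time_window")
  if (nrow(track) == 0) abort("`track` is empty.")
  if (nrow(density) == 0) abort("`density` is empty.")

  ids <- if ("shark_id" %in% names(track)) track$shark_id else
    rep(NA_character_, nrow(track))
  ct <- as.numeric(density$time)

  res <- purrr::map_dfr(seq_len(nrow(track)), function(i) {
    dt <- abs(ct - as.numeric(track$time[i]))
    near_t <- dt <= time_window
    if (!any(near_t)) return(NULL)
    dx <- density$x[near_t] - track$x[i]
    dy <- density$y[near_t] - track$y[i]
    inside <- (dx^2 + dy^2) < radius^2
    if (!any(inside)) return(NULL)
    cells <- density[near_t, ][inside, ]
    cells |>
      dplyr::group_by(.data$depth_bin) |>
      dplyr::summarise(mean_density = mean(.data$density),
                       n_cells = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(shark_id = ids[i], point_id = i,
                    time = track$time[i], x = track$x[i], y = track$y[i],
                    .before = 1)
  })
  matched_pts <- if (nrow(res) > 0) length(unique(res$point_id)) else 0
  n_unmatched <- nrow(track) - matched_pts
  if (n_unmatched > 0) {
    rlang::inform(sprintf("%d of %d locations had no in-buffer cells.",
                          n_unmatched, nrow(track)))
  }
  structure(res, class = c("matched_profile", class(tibble::tibble())),
            n_unmatched = n_unmatched, radius = radius,
            time_window = time_window)
}
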