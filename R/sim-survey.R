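#' Forward-model an echosounder survey over a synthetic scene
#'
#' Steams a boustrophedon set of cross-shelf transect lines over the scene
#' at the configured vessel speed and ping interval, and forward-models the
#' per-ping volume backscattering strength from the true prey field:
#' `Sv = 10 log10(n * sigma_bs) + noise`, where n is the local density
#' (ind m^-3), `sigma_bs = 10^(ts_db / 10)` the single-animal
#' backscattering cross-section, and the noise is additive Gaussian in the
#' dB domain. Samples sit at 1-m bin centres from the minimum sample depth
#' (nothing above 5 m is recorded) down to the seabed; the sample bin
#' containing the seabed carries a strong bottom echo. Cells with n = 0 or
#' with forward Sv below the detection floor are recorded as
#' below-detection (`Sv = -Inf`).
#'
#' @param scene A [simulate_scene()] result.
#' @param config The same [sim_config()]; the transect plan must overlap
#'   the scene.
#' @param t0 Survey start time (POSIXct, UTC).
#' @return A `ping_set`: a tibble with one row per (ping, sample) holding
#'   `ping`, `time`, `x`, `y`, `depth` (m), `sv_db` (dB re 1 m^-1) and
#'   `flag` (`ok`, `seabed`, `below_detection`).
#' @examples
#' cfg <- sim_config(n_patches = 1, noise_sd_db = 0, seed = 3,
#'                   track_duration_s = 600)
#' pings <- simulate_survey(simulate_scene(cfg), cfg)
#' dplyr::count(pings, flag)
#' @export
simulate_survey <- function(scene, config,
                            t0 = as.POSIXct("2018-05-19 01:00:00", tz = "UTC")) {
  if (!inherits(scene, "prey_scene")) abort("`scene` must be a prey_scene.")
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  with_local_seed(config$seed + 1L, forward_survey(scene, config, t0))
}

forward_survey <- function(scene, cfg, t0) {
  len <- min(cfg$line_length_m, cfg$extent_m)
  y_lines <- seq(cfg$line_spacing_m / 2, cfg$extent_m - cfg$line_spacing_m / 2,
                 by = cfg$line_spacing_m)
  if (length(y_lines) == 0 || len <= 0) {
    warn("Transect plan does not overlap the scene; returning empty ping set.")
    return(empty_ping_set())
  }

  step <- cfg$vessel_speed_ms * cfg$ping_interval_s
  along <- seq(0, len, by = step)
  plan <- purrr::imap_dfr(as.list(y_lines), function(yl, i) {
    xx <- if (i %% 2 == 1) along else rev(along)  # boustrophedon
    tibble::tibble(x = xx, y = yl)
  })
  n_ping <- nrow(plan)
  plan$ping <- seq_len(n_ping)
  plan$time <- t0 + (plan$ping - 1) * cfg$ping_interval_s

  sigma_bs <- db_to_linear(cfg$ts_db)
  samples <- purrr::pmap_dfr(plan, function(x, y, ping, time) {
    sb <- scene_seabed_at(scene, x, y)
    # water samples at 1-m bin centres strictly above the seabed, then one
    # bottom sample (the first bin centre at/under the seabed line) that
    # carries the strong seabed echo
    all_d <- seq(cfg$min_sample_depth_m + 0.5, cfg$max_range_m, by = cfg$sample_dz_m)
    depths <- all_d[all_d < sb]
    bottom <- all_d[all_d >= sb][1]
    if (!is.na(bottom)) depths <- c(depths, bottom)
    if (length(depths) == 0) return(NULL)
    n <- scene_density_at(scene, rep(x, length(depths)), rep(y, length(depths)), depths)
    sv <- linear_to_db(n * sigma_bs)
    finite <- is.finite(sv)
    if (cfg$noise_sd_db > 0 && any(finite)) {
      sv[finite] <- sv[finite] + rnorm(sum(finite), 0, cfg$noise_sd_db)
    }
    flag <- rep("ok", length(depths))
    is_bottom <- depths >= sb
    sv[is_bottom] <- cfg$seabed_echo_db
    flag[is_bottom] <- "seabed"
    below <- !is_bottom & (!is.finite(sv) | sv < cfg$detection_floor_db)
    sv[below] <- -Inf
    flag[below] <- "below_detection"
    tibble::tibble(ping = ping, time = time, x = x, y = y,
                   depth = depths, sv_db = sv, flag = flag)
  })
  structure(samples, class = c("ping_set", class(tibble::tibble())))
}

empty_ping_set <- function() {
  structure(
    tibble::tibble(ping = integer(0), time = as.POSIXct(character(0), tz = "UTC"),
                   x = numeric(0), y = numeric(0), depth = numeric(0),
                   sv_db = numeric(0), flag = character(0)),
    class = c("ping_set", class(tibble::tibble()))
  )
}
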