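#' Configuration for the synthetic reef-edge study system
#'
#' Bundles every tunable of the synthetic-data generator: the metric grid,
#' the bathymetry shape, the prey-patch model, the echosounder forward model
#' and the simulated shark movement model. A single integer `seed` fully
#' determines all generated objects.
#'
#' The defaults emulate the study setting the generator is modelled on: a
#' narrow forereef shelf with complex topography between 10 and ~50 m that
#' drops to low-relief seabed beyond 50 m, prey patches attached to
#' bathymetric features near the 50-m contour with volumetric densities
#' spanning ~0.01 to >1e5 ind m^-3, a 120 kHz downward-looking echosounder
#' surveying parallel transects (~3.5 km lines spaced ~1 km) at 10 knots
#' with a 0.5-s ping interval and no valid samples above 5 m, and
#' surface-oriented sharks whose horizontal preference for prey density is
#' the known simulation parameter `beta_pref`.
#'
#' @param extent_m Square domain edge length (m).
#' @param res_m Horizontal grid resolution (m); must be positive.
#' @param shore_depth_m,offshore_depth_m Seabed depth (m, positive down) at
#'   the inshore (x = 0) and offshore (x = extent) edges of the shelf.
#' @param n_features Number of bathymetric features (gutters/pinnacles)
#'   placed along the 50-m contour.
#' @param feature_relief_m Vertical relief amplitude of the features (m).
#' @param background_density Background prey density (ind m^-3).
#' @param n_patches Number of prey patches.
#' @param patch_radius_m Horizontal e-folding radius of a patch (m).
#' @param patch_sd_z_m Vertical e-folding scale of a patch (m).
#' @param patch_peak_density Peak density added by each patch (ind m^-3).
#' @param seabed_weight Near-seabed concentration weight in [0, 1]: 1 pins
#'   patch centres to the seabed, 0 places them uniformly in the column.
#' @param night_offset_m Upward vertical displacement of patch centres at
#'   night (m), emulating diel vertical migration.
#' @param noise_sd_db Single-ping Gaussian noise standard deviation in the
#'   dB domain (default 3 dB).
#' @param detection_floor_db Sv below this floor (dB re 1 m^-1) is recorded
#'   as below-detection and maps to density 0 downstream.
#' @param seabed_echo_db Sv of the injected seabed echo (dB re 1 m^-1).
#' @param line_length_m,line_spacing_m Transect plan: line length and
#'   spacing (m); lines run in +x (cross-shelf), stacked along y.
#' @param vessel_speed_ms Survey speed (m s^-1; default 10 kn).
#' @param ping_interval_s Seconds between pings.
#' @param sample_dz_m Vertical sample spacing (m).
#' @param min_sample_depth_m First valid sample depth (m); the transducer
#'   sits at 2.7 m and near-surface bubble entrainment is excluded, so
#'   nothing above 5 m is recorded.
#' @param max_range_m Maximum recording range (m).
#' @param ts_db Target strength (dB re 1 m^2) of one scatterer used by the
#'   forward model.
#' @param track_duration_s Simulated deployment length (s).
#' @param beta_pref Horizontal preference coefficient: step weights are
#'   proportional to `exp(beta_pref * z)` where z is the standardised
#'   water-column prey density of the candidate cell. 0 = no preference.
#' @param pref_lookahead_m Distance ahead at which candidate headings
#'   sample the prey field (m).
#' @param pref_smooth_m Gaussian smoothing scale applied to the column
#'   density before standardising, emulating sensory integration over
#'   patch scales.
#' @param shark_speed_ms Horizontal swimming speed (m s^-1).
#' @param vertical_speed_ms Constant descent/ascent rate (m s^-1).
#' @param surface_mean_s,bottom_mean_s Mean duration (s) of surface phases
#'   and of the at-depth phase of a dive.
#' @param deep_dive_prob Probability a dive targets the deep (40-60 m) mode
#'   rather than the shallow (<10 m) mode of the target-depth mixture.
#' @param fix_prob Per-second probability that a surface sample (< 1 m)
#'   yields a transmitted position fix.
#' @param detached_fixes Number of post-detachment floating-tag fixes to
#'   append at exact 30-min spacing (0 = none).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_patches = 2, seed = 7)
#' cfg$seed
#' @export
sim_config <- function(extent_m = 4000,
                       res_m = 50,
                       shore_depth_m = 10,
                       offshore_depth_m = 70,
                       n_features = 4,
                       feature_relief_m = 12,
                       background_density = 0.05,
                       n_patches = 5,
                       patch_radius_m = 300,
                       patch_sd_z_m = 6,
                       patch_peak_density = 2000,
                       seabed_weight = 0.8,
                       night_offset_m = 20,
                       noise_sd_db = 3,
                       detection_floor_db = -100,
                       seabed_echo_db = -10,
                       line_length_m = 3500,
                       line_spacing_m = 1000,
                       vessel_speed_ms = 5.144,
                       ping_interval_s = 0.5,
                       sample_dz_m = 1,
                       min_sample_depth_m = 5,
                       max_range_m = 200,
                       ts_db = -88.53,
                       track_duration_s = 6 * 3600,
                       beta_pref = 1,
                       pref_lookahead_m = 300,
                       pref_smooth_m = 600,
                       shark_speed_ms = 0.7,
                       vertical_speed_ms = 0.5,
                       surface_mean_s = 600,
                       bottom_mean_s = 120,
                       deep_dive_prob = 0.3,
                       fix_prob = 2e-4,
                       detached_fixes = 0,
                       seed = 1L) {
  assert_positive(extent_m, "extent_m")
  assert_positive(res_m, "res_m")
  assert_positive(shore_depth_m, "shore_depth_m")
  assert_positive(offshore_depth_m, "offshore_depth_m")
  assert_positive(line_length_m, "line_length_m")
  assert_positive(line_spacing_m, "line_spacing_m")
  assert_positive(ping_interval_s, "ping_interval_s")
  assert_positive(track_duration_s, "track_duration_s")
  assert_probability(fix_prob, "fix_prob")
  assert_probability(seabed_weight, "seabed_weight")
  assert_probability(deep_dive_prob, "deep_dive_prob")
  if (n_patches < 0 || n_patches != round(n_patches)) {
    abort("`n_patches` must be a non-negative integer.")
  }
  if (background_density < 0) abort("`background_density` must be >= 0.")
  if (noise_sd_db < 0) abort("`noise_sd_db` must be >= 0.")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  domain: %g x %g m @ %g m; shelf %g -> %g m\n",
              x$extent_m, x$extent_m, x$res_m, x$shore_depth_m,
              x$offshore_depth_m))
  cat(sprintf("  prey: %d patches (peak %g ind m^-3) on background %g\n",
              x$n_patches, x$patch_peak_density, x$background_density))
  cat(sprintf("  survey: %g-m lines / %g-m spacing, ping %g s, noise %g dB\n",
              x$line_length_m, x$line_spacing_m, x$ping_interval_s,
              x$noise_sd_db))
  cat(sprintf("  shark: %g h, beta_pref = %g; seed %d\n",
              x$track_duration_s / 3600, x$beta_pref, x$seed))
  invisible(x)
}
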