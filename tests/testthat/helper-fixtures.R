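# Shared fixtures, built once per test run. Small domains keep the suite
# fast; zero-noise configs give exact round trips.

quiet_cfg <- function(...) {
  sim_config(noise_sd_db = 0, detection_floor_db = -200, ...)
}

# one small scene + survey reused across acoustics tests
fixture_env <- new.env()

small_scene <- function() {
  if (is.null(fixture_env$scene)) {
    fixture_env$cfg <- quiet_cfg(extent_m = 2000, line_length_m = 2000,
                                 n_patches = 2, n_features = 2,
                                 shore_depth_m = 20, offshore_depth_m = 60,
                                 track_duration_s = 3600, seed = 11)
    fixture_env$scene <- simulate_scene(fixture_env$cfg)
  }
  list(cfg = fixture_env$cfg, scene = fixture_env$scene)
}

small_survey <- function() {
  if (is.null(fixture_env$pings)) {
    fx <- small_scene()
    fixture_env$pings <- simulate_survey(fx$scene, fx$cfg)
  }
  fixture_env$pings
}

# hand-built ping set: one ping, chosen Sv profile
make_ping <- function(depths, sv, ping = 1L,
                      t0 = as.POSIXct("2018-05-19 01:00:00", tz = "UTC")) {
  tibble::tibble(ping = ping, time = t0 + (ping - 1) * 0.5,
                 x = 0, y = 0, depth = depths, sv_db = sv, flag = "ok")
}

# 1-Hz tag record at constant or supplied depth/temperature
make_record <- function(n, depth = 5, temp = 27.5, shark_id = "WS1",
                        t0 = as.POSIXct("2018-05-19 03:00:00", tz = "UTC")) {
  tibble::tibble(shark_id = shark_id, time = t0 + seq_len(n) - 1,
                 depth_m = rep_len(depth, n), temp_c = rep_len(temp, n))
}

# brute-force Gaussian product-kernel KDE oracle (direct double loop)
brute_kde_2d <- function(gx, gy, px, py, hx, hy) {
  out <- matrix(0, length(gx), length(gy))
  for (i in seq_along(gx)) {
    for (j in seq_along(gy)) {
      out[i, j] <- mean(dnorm((gx[i] - px) / hx) * dnorm((gy[j] - py) / hy)) /
        (hx * hy)
    }
  }
  out
}

brute_kde_3d <- function(gx, gy, gz, px, py, pz, h) {
  out <- array(0, c(length(gx), length(gy), length(gz)))
  for (i in seq_along(gx)) {
    for (j in seq_along(gy)) {
      for (k in seq_along(gz)) {
        out[i, j, k] <- mean(
          dnorm((gx[i] - px) / h[1]) * dnorm((gy[j] - py) / h[2]) *
            dnorm((gz[k] - pz) / h[3])
        ) / prod(h)
      }
    }
  }
  out
}

# simulate one TAD-vs-density dataset with known fixed slope and
# random-intercept sd, for the mixed-model recovery checks
simulate_tad_data <- function(beta1, sd_b, n_sharks = 10, n_bins = 50,
                              sigma = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("WS%02d", seq_len(n_sharks))
  d <- tidyr::expand_grid(shark_id = ids,
                          depth_bin = 4 + seq_len(n_bins))
  b <- rnorm(n_sharks, 0, sd_b)
  names(b) <- ids
  d$density <- runif(nrow(d), 0, 10)
  d$tad_s <- 10 + b[d$shark_id] + beta1 * d$density + rnorm(nrow(d), 0, sigma)
  d
}
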