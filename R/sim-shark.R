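#' Simulate a surface-oriented shark track over a scene
#'
#' Generates a 1-Hz depth/temperature record and a sparse series of
#' position fixes for one simulated shark. The vertical process is a
#' two-state renewal: surface phases (depth < 1 m) alternate with dives
#' that descend at a constant vertical speed to a target depth drawn from a
#' mixture favouring the near-surface (< 10 m) and the 40-60 m layer, hold,
#' and ascend. The horizontal process is a correlated random walk whose
#' candidate headings are weighted by `exp(beta_pref * z)`, with z the
#' standardised water-column prey density ahead of the animal, so the
#' preference for prey is a known simulation parameter. Fixes are emitted
#' only at seconds when the animal is within 1 m of the surface, thinned by
#' the fix-acquisition probability; a deployment fix at the start is always
#' present, and optional post-detachment floating-tag fixes are appended at
#' exact 30-min spacing.
#'
#' @param scene A [simulate_scene()] result.
#' @param config The same [sim_config()].
#' @param shark_id Identifier written into both outputs.
#' @param t0 Deployment time (POSIXct, UTC).
#' @return A list with `record` (tibble: shark_id, time, depth_m, temp_c,
#'   light, x, y — the true positions are retained as simulation truth) and
#'   `fixes` (tibble: shark_id, time, x, y, source, attached).
#' @examples
#' cfg <- sim_config(track_duration_s = 1800, seed = 4)
#' sh <- simulate_shark(simulate_scene(cfg), cfg)
#' nrow(sh$record)
#' @export
simulate_shark <- function(scene, config, shark_id = "WS1",
                           t0 = as.POSIXct("2018-05-19 02:00:00", tz = "UTC")) {
  if (!inherits(scene, "prey_scene")) abort("`scene` must be a prey_scene.")
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  with_local_seed(config$seed + 2L, walk_shark(scene, config, shark_id, t0))
}

walk_shark <- function(scene, cfg, shark_id, t0) {
  n <- as.integer(cfg$track_duration_s)
  # standardised, patch-scale-smoothed column density drives the
  # horizontal preference (sensory integration over ~ pref_smooth_m)
  cd <- gaussian_smooth_2d(scene$column_density, cfg$pref_smooth_m / cfg$res_m)
  z_std <- (cd - mean(cd)) / max(sd(cd), 1e-12)

  x <- numeric(n); y <- numeric(n); depth <- numeric(n)
  x[1] <- runif(1, 0.25, 0.75) * cfg$extent_m
  y[1] <- runif(1, 0.25, 0.75) * cfg$extent_m
  heading <- runif(1, 0, 2 * pi)

  # vertical renewal process
  state <- "surface"
  state_left <- max(60, stats::rexp(1, 1 / cfg$surface_mean_s))
  target <- 0.5
  depth[1] <- 0.5

  lookahead <- cfg$pref_lookahead_m
  cand <- seq(0, 2 * pi, length.out = 17)[-17]
  resample_every <- 30

  for (t in 2:n) {
    if ((t - 1) %% resample_every == 0) {
      nx <- pmin(pmax(x[t - 1] + lookahead * cos(cand), 1), cfg$extent_m - 1)
      ny <- pmin(pmax(y[t - 1] + lookahead * sin(cand), 1), cfg$extent_m - 1)
      zc <- z_std[cbind(nearest_index(nx, scene$xs), nearest_index(ny, scene$ys))]
      # persistence + prey preference
      w <- exp(cfg$beta_pref * zc + 2 * cos(cand - heading))
      heading <- cand[sample.int(length(cand), 1, prob = w / sum(w))]
    }
    heading <- heading + rnorm(1, 0, 0.1)
    x[t] <- x[t - 1] + cfg$shark_speed_ms * cos(heading)
    y[t] <- y[t - 1] + cfg$shark_speed_ms * sin(heading)
    if (x[t] < 1 || x[t] > cfg$extent_m - 1) {
      heading <- pi - heading
      x[t] <- pmin(pmax(x[t], 1), cfg$extent_m - 1)
    }
    if (y[t] < 1 || y[t] > cfg$extent_m - 1) {
      heading <- -heading
      y[t] <- pmin(pmax(y[t], 1), cfg$extent_m - 1)
    }

    state_left <- state_left - 1
    if (state_left <= 0) {
      if (state == "surface") {
        state <- "dive"
        sb <- scene_seabed_at(scene, x[t], y[t])
        target <- if (runif(1) < cfg$deep_dive_prob) runif(1, 40, 60) else runif(1, 2, 10)
        target <- min(target, sb - 1)
        state_left <- Inf  # ends when back at surface
      } else {
        state <- "surface"
        target <- 0.5
        state_left <- max(60, stats::rexp(1, 1 / cfg$surface_mean_s))
      }
    }
    sb_here <- scene_seabed_at(scene, x[t], y[t])
    goal <- min(target, sb_here - 1)
    step <- cfg$vertical_speed_ms
    depth[t] <- depth[t - 1] + sign(goal - depth[t - 1]) * min(step, abs(goal - depth[t - 1]))
    depth[t] <- min(max(depth[t], 0), sb_here - 0.5)
    if (state == "dive" && abs(depth[t] - goal) < step) {
      # arrived: hold, then resurface by switching the target to 0
      if (target > 0.6 && runif(1) < 1 / max(cfg$bottom_mean_s, 1)) target <- 0.5
      if (target <= 0.6 && depth[t] <= 1) {
        state <- "surface"
        state_left <- max(60, stats::rexp(1, 1 / cfg$surface_mean_s))
      }
    }
  }

  times <- t0 + seq_len(n) - 1
  temp <- 28 - 0.02 * depth + rnorm(n, 0, 0.05)
  light <- exp(-0.15 * depth) * pmax(0, sin(pi * ((as.numeric(times) / 86400) %% 1)))

  record <- tibble::tibble(
    shark_id = shark_id, time = times,
    depth_m = depth, temp_c = temp, light = light, x = x, y = y
  )

  at_surface <- which(depth < 1)
  got_fix <- at_surface[runif(length(at_surface)) < cfg$fix_prob]
  got_fix <- setdiff(got_fix, 1L)
  fixes <- tibble::tibble(
    shark_id = shark_id,
    time = c(times[1], times[got_fix]),
    x = c(x[1], x[got_fix]),
    y = c(y[1], y[got_fix]),
    source = c("deployment", rep("gps", length(got_fix))),
    attached = TRUE
  )
  if (cfg$detached_fixes > 0) {
    drift <- tibble::tibble(
      shark_id = shark_id,
      time = times[n] + 1800 * seq_len(cfg$detached_fixes),
      x = x[n] + cumsum(rnorm(cfg$detached_fixes, 0, 30)),
      y = y[n] + cumsum(rnorm(cfg$detached_fixes, 0, 30)),
      source = "argos",
      attached = FALSE
    )
    fixes <- dplyr::bind_rows(fixes, drift)
  }
  list(record = record, fixes = fixes)
}

# separable Gaussian blur of a matrix; sd in cell units. The kernel is
# truncated to the axis length on small domains.
gaussian_smooth_2d <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  smooth_vec <- function(v) {
    half <- min(ceiling(3 * sd_cells), length(v) - 1)
    if (half < 1) return(v)
    k <- dnorm(seq(-half, half), 0, sd_cells)
    k <- k / sum(k)
    # reflect-pad so edges keep unit kernel mass
    vp <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1]))
    as.numeric(stats::filter(vp, k, sides = 2))[half + seq_along(v)]
  }
  m2 <- apply(m, 2, smooth_vec)
  t(apply(m2, 1, smooth_vec))
}
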