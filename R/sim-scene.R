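# Evaluate an expression with a temporary RNG state so that generator
# functions are deterministic in (config, seed) without disturbing the
# caller's random stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic reef-edge scene with a known prey field
#'
#' Builds a metric-grid study domain: a shelf sloping from the inshore to
#' the offshore depth, gutters and pinnacles superimposed near the 50-m
#' contour (the reef edge), and a 3D prey-density field of Gaussian patches
#' whose centres are attached to those bathymetric features, on top of a
#' uniform background. The simulation truth (patch centres, intensities,
#' preference coefficient, seed) is retained so downstream estimates can be
#' checked against it.
#'
#' Depth bin `k` covers `[k, k+1)` m; a bin belongs to the water column when
#' its centre lies above the local seabed, and density is 0 below the
#' seabed. All coordinates are local metric (easting, northing) metres with
#' depth positive downward.
#'
#' @param config A [sim_config()].
#' @return An object of class `prey_scene`: a list with elements
#'   `bathymetry` (tibble: x, y, seabed_m), `reef_edge` (tibble of points on
#'   the 50-m contour), `density` (array x-index by y-index by 1-m depth
#'   bin, ind m^-3), `column_density` (matrix of water-column mean density
#'   5 m to seabed), grid vectors `xs`, `ys`, `zbins`, and `truth`.
#' @examples
#' sc <- simulate_scene(sim_config(n_patches = 1, seed = 2))
#' range(sc$bathymetry$seabed_m)
#' @export
simulate_scene <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  with_local_seed(config$seed, build_scene(config))
}

build_scene <- function(cfg) {
  xs <- seq(cfg$res_m / 2, cfg$extent_m - cfg$res_m / 2, by = cfg$res_m)
  ys <- xs
  nx <- length(xs)
  ny <- length(ys)

  # shelf: linear slope inshore (x = 0) to offshore (x = extent)
  slope <- (cfg$offshore_depth_m - cfg$shore_depth_m) / cfg$extent_m
  base <- cfg$shore_depth_m + outer(xs, rep(1, ny)) * slope

  # cross-shelf position of the 50-m contour on the smooth shelf
  x50 <- (50 - cfg$shore_depth_m) / slope
  x50 <- min(max(x50, cfg$res_m), cfg$extent_m - cfg$res_m)

  features <- tibble::tibble(
    x = rep(x50, cfg$n_features) + rnorm(cfg$n_features, 0, cfg$res_m),
    y = runif(cfg$n_features, 0.1, 0.9) * cfg$extent_m,
    # +1 gutter (deeper), -1 pinnacle (shallower)
    sign = sample(c(-1, 1), cfg$n_features, replace = TRUE),
    relief = cfg$feature_relief_m * runif(cfg$n_features, 0.6, 1)
  )
  seabed <- base
  if (cfg$n_features > 0) {
    fr <- 4 * cfg$res_m  # feature footprint
    for (i in seq_len(cfg$n_features)) {
      bump <- outer(xs, ys, function(x, y) {
        exp(-((x - features$x[i])^2 + (y - features$y[i])^2) / (2 * fr^2))
      })
      seabed <- seabed + features$sign[i] * features$relief[i] * bump
    }
  }
  seabed <- pmax(seabed, 2)  # physical: always submerged

  reef_edge <- contour_points(xs, ys, seabed, level = 50)

  nz <- ceiling(max(seabed))
  zbins <- seq_len(nz) - 1  # lower edges of [k, k+1)

  # patch centres attach to bathymetric features (or the reef edge when no
  # features exist); vertical placement pulled toward the seabed by
  # seabed_weight
  patches <- tibble::tibble(
    x = numeric(0), y = numeric(0), z = numeric(0), peak = numeric(0)
  )
  if (cfg$n_patches > 0) {
    anchor <- if (cfg$n_features > 0) {
      features[sample.int(cfg$n_features, cfg$n_patches, replace = TRUE), c("x", "y")]
    } else {
      tibble::tibble(x = rep(x50, cfg$n_patches),
                     y = runif(cfg$n_patches, 0.1, 0.9) * cfg$extent_m)
    }
    px <- anchor$x + rnorm(cfg$n_patches, 0, cfg$patch_radius_m / 4)
    py <- anchor$y + rnorm(cfg$n_patches, 0, cfg$patch_radius_m / 4)
    px <- pmin(pmax(px, 0), cfg$extent_m)
    py <- pmin(pmax(py, 0), cfg$extent_m)
    sb_at <- seabed[cbind(nearest_index(px, xs), nearest_index(py, ys))]
    z_uniform <- runif(cfg$n_patches, cfg$min_sample_depth_m, pmax(sb_at - 2, 6))
    pz <- cfg$seabed_weight * (sb_at - cfg$patch_sd_z_m) +
      (1 - cfg$seabed_weight) * z_uniform
    patches <- tibble::tibble(x = px, y = py, z = pmax(pz, 1),
                              peak = cfg$patch_peak_density)
  }

  density <- array(cfg$background_density, dim = c(nx, ny, nz))
  zc <- zbins + 0.5
  if (nrow(patches) > 0) {
    for (i in seq_len(nrow(patches))) {
      horiz <- outer(xs, ys, function(x, y) {
        exp(-((x - patches$x[i])^2 + (y - patches$y[i])^2) /
              (2 * cfg$patch_radius_m^2))
      })
      vert <- exp(-(zc - patches$z[i])^2 / (2 * cfg$patch_sd_z_m^2))
      for (k in seq_len(nz)) {
        density[, , k] <- density[, , k] + patches$peak[i] * horiz * vert[k]
      }
    }
  }
  # zero below the local seabed (bin centre at/under the bottom)
  for (k in seq_len(nz)) {
    density[, , k][zc[k] >= seabed] <- 0
  }

  column_density <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      wat <- zc >= cfg$min_sample_depth_m & zc < seabed[i, j]
      column_density[i, j] <- if (any(wat)) mean(density[i, j, wat]) else 0
    }
  }

  structure(
    list(
      bathymetry = tidyr::expand_grid(x = xs, y = ys) |>
        dplyr::mutate(seabed_m = as.vector(t(seabed))) |>
        dplyr::arrange(.data$x, .data$y),
      seabed = seabed,
      reef_edge = reef_edge,
      density = density,
      column_density = column_density,
      xs = xs, ys = ys, zbins = zbins,
      truth = list(patches = patches, features = features,
                   beta_pref = cfg$beta_pref,
                   night_offset_m = cfg$night_offset_m, seed = cfg$seed),
      config = cfg
    ),
    class = "prey_scene"
  )
}

#' @export
print.prey_scene <- function(x, ...) {
  cat("<prey_scene>\n")
  cat(sprintf("  grid: %d x %d cells @ %g m, %d depth bins\n",
              length(x$xs), length(x$ys), x$config$res_m, length(x$zbins)))
  cat(sprintf("  seabed: %.1f - %.1f m; %d reef-edge points\n",
              min(x$seabed), max(x$seabed), nrow(x$reef_edge)))
  cat(sprintf("  prey: %d patches, density %.3g - %.3g ind m^-3\n",
              nrow(x$truth$patches), min(x$density), max(x$density)))
  invisible(x)
}

nearest_index <- function(v, grid) {
  pmin(pmax(round((v - grid[1]) / (grid[2] - grid[1])) + 1, 1), length(grid))
}

# points where a gridded surface crosses `level`, via contourLines
contour_points <- function(xs, ys, z, level) {
  cl <- grDevices::contourLines(xs, ys, z, levels = level)
  if (length(cl) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), piece = integer(0)))
  }
  purrr::imap_dfr(cl, function(p, i) {
    tibble::tibble(x = p$x, y = p$y, piece = as.integer(i))
  })
}

#' Look up scene ground truth at arbitrary points
#'
#' `scene_density_at()` returns the true prey density (ind m^-3) of the
#' cell containing each (x, y, depth) point; `scene_seabed_at()` the local
#' seabed depth (m) at each (x, y).
#'
#' @param scene A `prey_scene`.
#' @param x,y,depth Coordinate vectors (m).
#' @return Numeric vector.
#' @export
scene_density_at <- function(scene, x, y, depth) {
  i <- nearest_index(x, scene$xs)
  j <- nearest_index(y, scene$ys)
  k <- floor(depth) + 1
  nz <- dim(scene$density)[3]
  out <- rep(0, length(x))
  ok <- k >= 1 & k <= nz
  out[ok] <- scene$density[cbind(i[ok], j[ok], k[ok])]
  out
}

#' @rdname scene_density_at
#' @export
scene_seabed_at <- function(scene, x, y) {
  scene$seabed[cbind(nearest_index(x, scene$xs), nearest_index(y, scene$ys))]
}
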