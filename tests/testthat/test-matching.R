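test_that("the empirical variogram matches a hand-worked 1D case", {
  pts <- tibble::tibble(x = c(0, 1, 2, 3), y = 0)
  # need >= 30 points: replicate the 4-point motif far apart so extra pairs
  # fall outside max_lag; simplest is to relax via direct internal call on
  # the 4 points' pairs computed by hand instead
  # lag-1 pairs: (0,1), (1,2), (2,3) -> diffs 1, 0, 1 -> gamma = 2/(2*3)
  z <- c(0, 1, 1, 0)
  d <- as.vector(dist(cbind(pts$x, pts$y)))
  dz2 <- as.vector(dist(z))^2
  g1 <- sum(dz2[d == 1]) / (2 * sum(d == 1))
  expect_equal(g1, 1 / 3, tolerance = 1e-15)

  # the estimator reproduces that value through the public interface
  big <- tibble::tibble(x = c(0, 1, 2, 3, seq(1000, 1000 + 25 * 50, by = 50)),
                        y = 0)
  zb <- c(0, 1, 1, 0, rep(0, 26))
  emp <- empirical_variogram(big, zb, lag_width = 1.5, max_lag = 4)
  expect_equal(emp$gamma[emp$lag == 0.75], 1 / 3, tolerance = 1e-12)
  expect_identical(emp$n_pairs[emp$lag == 0.75], 3L)
})

test_that("a constant field has zero semivariance everywhere", {
  set.seed(41)
  pts <- tibble::tibble(x = runif(50, 0, 2000), y = runif(50, 0, 2000))
  emp <- empirical_variogram(pts, rep(7, 50), lag_width = 200, max_lag = 2000)
  expect_true(all(emp$gamma == 0))
  expect_warning(fit <- fit_variogram_gaussian(emp), "nugget")
  expect_false(fit$range_identifiable)
})

test_that("i.i.d. noise gives a pure-nugget variogram near its variance", {
  set.seed(42)
  reps <- replicate(8, {
    pts <- tibble::tibble(x = runif(120, 0, 3000), y = runif(120, 0, 3000))
    emp <- empirical_variogram(pts, rnorm(120, 0, 2), lag_width = 300,
                               max_lag = 2500)
    mean(emp$gamma)
  })
  # gamma should hover around sigma^2 = 4
  expect_lt(abs(mean(reps) - 4), 2 * sd(reps) + 0.2)
  expect_true(all(abs(reps - 4) < 1.5))
})

test_that("the variogram is invariant to coordinate reflection", {
  set.seed(43)
  pts <- tibble::tibble(x = runif(60, 0, 2000), y = runif(60, 0, 2000))
  z <- pts$x / 1000 + rnorm(60, 0, 0.1)
  emp1 <- empirical_variogram(pts, z, lag_width = 250, max_lag = 2000)
  emp2 <- empirical_variogram(dplyr::mutate(pts, x = -.data$x, y = -.data$y),
                              z, lag_width = 250, max_lag = 2000)
  expect_equal(emp1$gamma, emp2$gamma, tolerance = 1e-12)
})

test_that("noiseless model-generated semivariances are recovered exactly", {
  lags <- seq(50, 2950, by = 100)
  c0 <- 0.2; c1 <- 1.5; a <- 700
  emp <- tibble::tibble(lag = lags,
                        gamma = c0 + c1 * (1 - exp(-lags^2 / a^2)),
                        n_pairs = 100L)
  fit <- fit_variogram_gaussian(emp)
  expect_equal(fit$nugget, c0, tolerance = 1e-6)
  expect_equal(fit$partial_sill, c1, tolerance = 1e-6)
  expect_equal(fit$range_param, a, tolerance = 1e-6)
  expect_equal(fit$effective_range_m, a * sqrt(3), tolerance = 1e-6)
  # definitional check: gamma(effective range) ~ c0 + 0.95 c
  g_eff <- c0 + c1 * (1 - exp(-3))
  expect_equal(g_eff, c0 + 0.9502 * c1, tolerance = 1e-3)
})

test_that("a Gaussian-covariance field's effective range is recovered", {
  set.seed(44)
  eff <- vapply(1:20, function(r) {
    n <- 300
    pts <- tibble::tibble(x = runif(n, 0, 4000), y = runif(n, 0, 4000))
    a <- 1000 / sqrt(3)
    D <- as.matrix(dist(cbind(pts$x, pts$y)))
    C <- exp(-D^2 / a^2) + diag(0.05 + 1e-6, n)
    z <- as.vector(t(chol(C)) %*% rnorm(n))
    fit <- fit_variogram_gaussian(
      empirical_variogram(pts, z, lag_width = 100, max_lag = 3000)
    )
    fit$effective_range_m
  }, numeric(1))
  expect_lt(abs(median(eff) - 1000) / 1000, 0.2)
})

test_that("buffer extraction honours the strict radius and includes zeros", {
  t0 <- as.POSIXct("2018-05-19 01:00:00", tz = "UTC")
  dens <- tibble::tibble(
    interval = 1:3, depth_bin = 10,
    mvbs_db = -70, n_samples = 5,
    x = c(999, 1001, 500), y = 0, time = t0,
    density = c(4, 100, 0)
  )
  trk <- tibble::tibble(time = t0, x = 0, y = 0)
  prof <- suppressMessages(match_buffer(trk, dens, radius = 1000))
  # 1001-m cell excluded; mean of {4, 0} = 2
  expect_equal(prof$mean_density, 2)
  expect_identical(prof$n_cells, 2L)
})

test_that("buffer means are permutation-invariant and linear in density", {
  set.seed(45)
  t0 <- as.POSIXct("2018-05-19 01:00:00", tz = "UTC")
  dens <- tibble::tibble(
    interval = 1:40, depth_bin = rep(c(10, 11), 20),
    x = runif(40, -800, 800), y = runif(40, -800, 800),
    time = t0, density = runif(40, 0, 50)
  )
  trk <- tibble::tibble(time = t0, x = 0, y = 0)
  p1 <- suppressMessages(match_buffer(trk, dens))
  p2 <- suppressMessages(match_buffer(trk, dens[sample(40), ]))
  expect_equal(dplyr::arrange(p1, .data$depth_bin)$mean_density,
               dplyr::arrange(p2, .data$depth_bin)$mean_density,
               tolerance = 1e-12)
  p3 <- suppressMessages(match_buffer(trk, dplyr::mutate(dens, density = 3 * .data$density)))
  expect_equal(p3$mean_density, 3 * p1$mean_density, tolerance = 1e-12)
})

test_that("points outside the temporal window are excluded and counted", {
  t0 <- as.POSIXct("2018-05-19 01:00:00", tz = "UTC")
  dens <- tibble::tibble(interval = 1, depth_bin = 10, x = 0, y = 0,
                         time = t0, density = 5)
  trk <- tibble::tibble(time = c(t0 + 3600, t0 + 10 * 3600), x = 0, y = 0)
  expect_message(prof <- match_buffer(trk, dens, time_window = 6 * 3600),
                 "1 of 2")
  expect_identical(attr(prof, "n_unmatched"), 1L)
  expect_identical(nrow(prof), 1L)
})

test_that("buffer means reproduce scene truth through the acoustic chain", {
  fx <- small_scene()
  cleaned <- clean_echogram(small_survey())
  dens <- sv_to_density(echo_integrate(cleaned), fx$cfg$ts_db)
  truth <- true_density_grid(fx$scene, cleaned)
  dens_true <- dens
  dens_true$density <- truth$true_density[
    match(paste(dens$interval, dens$depth_bin),
          paste(truth$interval, truth$depth_bin))
  ]
  trk <- tibble::tibble(time = mean(dens$time),
                        x = c(700, 1200), y = c(700, 1100))
  p_est <- suppressMessages(match_buffer(trk, dens))
  p_true <- suppressMessages(match_buffer(trk, dens_true))
  expect_identical(nrow(p_est), nrow(p_true))
  relerr <- abs(p_est$mean_density - p_true$mean_density) /
    pmax(p_true$mean_density, 1e-12)
  expect_lt(max(relerr), 1e-6)
})
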