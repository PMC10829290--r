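test_that("the seabed detector finds an injected bottom within one sample", {
  depths <- seq(5.5, 60.5, by = 1)
  sv <- rep(-75, length(depths))
  sv[depths == 45.5] <- -12          # strong bottom echo at 45.0-46.0 m
  sv[depths > 45.5] <- -60           # sub-bottom tail, below threshold
  pings <- dplyr::bind_rows(lapply(1:7, function(p) make_ping(depths, sv, p)))
  cleaned <- clean_echogram(pings)
  expect_true(all(abs(cleaned$seabed_m - 45.5) <= 1))
  expect_true(all(cleaned$flag[cleaned$depth == 45.5] == "seabed"))
  expect_true(all(cleaned$flag[cleaned$depth == 30.5] == "ok"))
})

test_that("pings without a strong echo get no seabed flag, only surface exclusion", {
  depths <- seq(2.5, 40.5, by = 1)
  pings <- make_ping(depths, rep(-75, length(depths)))
  cleaned <- clean_echogram(pings)
  expect_true(all(is.na(cleaned$seabed_m)))
  expect_true(all(cleaned$flag[cleaned$depth < 5] == "surface"))
  expect_false(any(cleaned$flag == "seabed"))
})

test_that("a ping entirely above the exclusion depth is fully flagged", {
  pings <- make_ping(c(1.5, 2.5, 3.5), c(-70, -70, -70))
  cleaned <- clean_echogram(pings)
  expect_true(all(cleaned$flag == "surface"))
})

test_that("trawl windows remove their pings from integration", {
  depths <- seq(5.5, 20.5, by = 1)
  pings <- dplyr::bind_rows(lapply(1:10, function(p) make_ping(depths, -70, p)))
  tw <- tibble::tibble(start = pings$time[1], end = pings$time[1] + 2)
  cleaned <- clean_echogram(pings, trawl_windows = tw)
  # pings at 0.5-s spacing: the 2-s window catches the first five
  expect_identical(sum(cleaned$flag == "trawl"), 5L * length(depths))
  grid <- echo_integrate(cleaned)
  expect_true(all(grid$n_samples == 5))
})

test_that("echo integration averages in the linear domain", {
  depths <- c(10.5, 10.6)
  pings <- make_ping(depths, c(-70, -80))
  grid <- echo_integrate(clean_echogram(pings))
  expect_equal(grid$mvbs_db, 10 * log10((1e-7 + 1e-8) / 2), tolerance = 1e-10)
  expect_equal(grid$mvbs_db, -72.60, tolerance = 1e-3)

  constant <- echo_integrate(clean_echogram(make_ping(seq(5.5, 30.5, 1), -70)))
  expect_true(all(abs(constant$mvbs_db - -70) < 1e-12))

  # property: MVBS equals the dB of the brute-force linear mean
  set.seed(9)
  sv <- runif(24, -90, -60)
  p <- make_ping(seq(5.5, 28.5, 1), sv)   # one 30-m cell
  g1 <- echo_integrate(clean_echogram(p), interval_s = 30, bin_m = 30)
  expect_identical(nrow(g1), 1L)
  expect_equal(g1$mvbs_db, 10 * log10(mean(10^(sv / 10))), tolerance = 1e-12)
})

test_that("a cell of only below-detection samples gets the -Inf sentinel and density 0", {
  p <- make_ping(c(10.5, 11.5), c(-Inf, -Inf))
  p$flag <- "below_detection"
  g <- echo_integrate(p)
  expect_true(all(g$mvbs_db == -Inf))
  d <- sv_to_density(g, -88.53)
  expect_true(all(d$density == 0))
})

test_that("NASC matches the closed form for a constant layer", {
  # uniform sv = 1e-6 m^-1 over a 10-m layer: 4 pi 1852^2 * 1e-5
  depths <- seq(5.5, 14.5, by = 1)
  pings <- make_ping(depths, -60)
  nasc <- compute_nasc(echo_integrate(clean_echogram(pings)))
  expect_equal(nasc$nasc, 4 * pi * 1852^2 * 1e-5, tolerance = 1e-12)
  expect_equal(nasc$nasc, 431.0, tolerance = 1e-3)
})

test_that("NASC of an all-below-detection layer is zero", {
  p <- make_ping(c(10.5, 11.5), c(-Inf, -Inf))
  p$flag <- "below_detection"
  nasc <- compute_nasc(echo_integrate(p))
  expect_identical(nasc$nasc, 0)
})

test_that("NASC is additive over a depth partition", {
  cfg <- quiet_cfg(extent_m = 2000, line_length_m = 2000, n_patches = 2,
                   shore_depth_m = 35, offshore_depth_m = 60, seed = 13)
  grid <- echo_integrate(clean_echogram(simulate_survey(simulate_scene(cfg), cfg)))
  shallow <- compute_nasc(grid, depth_range = c(5, 30))
  deep <- compute_nasc(grid, depth_range = c(30, Inf))
  full <- compute_nasc(grid, depth_range = c(5, Inf))
  j <- dplyr::inner_join(
    dplyr::inner_join(shallow, deep, by = "interval_500",
                      suffix = c("_s", "_d")),
    full, by = "interval_500"
  )
  expect_gt(nrow(j), 2)
  expect_lt(max(abs(j$nasc_s + j$nasc_d - j$nasc) / j$nasc), 1e-3)
})

test_that("NASC is invariant to sub-binning a piecewise-constant field", {
  # 0.25-m samples of a field constant on 1-m pieces
  depths <- seq(5.125, 25, by = 0.25)
  piece_sv <- rep(runif(20, -80, -60), each = 4)
  pings <- dplyr::bind_rows(lapply(1:3, function(p) make_ping(depths, piece_sv, p)))
  cleaned <- clean_echogram(pings)
  n1 <- compute_nasc(echo_integrate(cleaned, bin_m = 1))
  n05 <- compute_nasc(echo_integrate(cleaned, bin_m = 0.5))
  expect_lt(abs(n1$nasc - n05$nasc) / n1$nasc, 1e-3)
})

test_that("density scaling obeys the decade identities and equivariance", {
  ts <- -88.53
  g <- echo_integrate(clean_echogram(make_ping(c(10.5, 20.5), c(ts, ts + 10))))
  d <- sv_to_density(g, ts)
  expect_equal(sort(d$density), c(1, 10), tolerance = 1e-12)

  # adding c dB to every MVBS multiplies density by 10^(c/10)
  g2 <- g
  g2$mvbs_db <- g$mvbs_db + 7
  d2 <- sv_to_density(g2, ts)
  expect_equal(d2$density, d$density * 10^(0.7), tolerance = 1e-12)
})

test_that("scaling by a non-finite TS is refused", {
  g <- echo_integrate(clean_echogram(make_ping(c(10.5), -70)))
  expect_error(sv_to_density(g, -Inf), "not finite")
})

test_that("the acoustic inversion reproduces cell-averaged truth without noise", {
  fx <- small_scene()
  cleaned <- clean_echogram(small_survey())
  grid <- echo_integrate(cleaned)
  dens <- sv_to_density(grid, fx$cfg$ts_db)
  truth <- true_density_grid(fx$scene, cleaned)
  j <- dplyr::inner_join(dens, truth, by = c("interval", "depth_bin"))
  expect_identical(nrow(j), nrow(grid))
  relerr <- abs(j$density - j$true_density) / pmax(j$true_density, 1e-12)
  expect_lt(max(relerr), 1e-6)
})
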