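t0 <- as.POSIXct("2018-05-19 00:00:00", tz = "UTC")

test_that("the detachment filter flags a trailing run of regular fixes", {
  irregular <- t0 + c(0, 700, 2500, 5200, 6700)
  regular <- max(irregular) + 900 + 1800 * (0:5)
  fx <- tibble::tibble(time = c(irregular, regular))
  out <- filter_detached(fx)
  expect_identical(out$attached, c(rep(TRUE, 5), rep(FALSE, 6)))
})

test_that("irregular-only and degenerate fix series stay attached", {
  fx <- tibble::tibble(time = t0 + c(0, 700, 2500, 5200, 9000))
  expect_true(all(filter_detached(fx)$attached))
  single <- tibble::tibble(time = t0)
  expect_true(filter_detached(single)$attached)
  empty <- tibble::tibble(time = t0[0])
  expect_identical(nrow(filter_detached(empty)), 0L)
})

test_that("regular gaps within tolerance count toward detachment", {
  # gaps of 29-31 min are 'matching the programmed interval'
  fx <- tibble::tibble(time = t0 + c(0, 500, cumsum(c(3000, 1740, 1860, 1800))))
  out <- filter_detached(fx)
  # gaps: 500, 2500, 1740, 1860, 1800 -> trailing regular run of 3 gaps,
  # so the 4 fixes from the run's start onward are detached
  expect_identical(out$attached, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("dwell histograms place constant records in one bin and conserve time", {
  rec <- make_record(600, depth = 3.2)
  tad <- compute_tad(rec)
  expect_identical(tad$bin, 3)
  expect_identical(tad$seconds, 600)
  expect_identical(tad$fraction, 1)

  tat <- compute_tat(make_record(1000, temp = 27.5))
  expect_identical(tat$bin, 27)
  expect_identical(tat$seconds, 1000)
})

test_that("a linear descent spreads dwell time evenly across bins", {
  rec <- make_record(100)
  rec$depth_m <- (0:99) * 0.1   # 0 to 10 m over 100 s
  tad <- compute_tad(rec)
  expect_identical(tad$bin, as.numeric(0:9))
  expect_true(all(tad$seconds == 10))
  expect_equal(sum(tad$fraction), 1, tolerance = 1e-12)
})

test_that("day and night histograms partition the full record", {
  set.seed(21)
  # 09:00-15:00 UTC straddles local sunset at the study longitude
  rec <- make_record(6 * 3600, t0 = as.POSIXct("2018-05-19 09:00:00", tz = "UTC"))
  rec$depth_m <- runif(nrow(rec), 0, 40)
  all_h <- compute_tad(rec, "all")
  day_h <- compute_tad(rec, "day")
  night_h <- compute_tad(rec, "night")
  merged <- dplyr::full_join(day_h, night_h, by = "bin", suffix = c("_d", "_n")) |>
    dplyr::mutate(seconds = dplyr::coalesce(.data$seconds_d, 0) +
                    dplyr::coalesce(.data$seconds_n, 0)) |>
    dplyr::arrange(.data$bin)
  expect_equal(merged$seconds, all_h$seconds)
  expect_equal(sum(all_h$seconds), nrow(rec))
})

test_that("a constructed night record reproduces a 20/80 temperature split", {
  # 02:00 local (18:00 UTC) is night at the study longitude
  night0 <- as.POSIXct("2018-05-18 18:00:00", tz = "UTC")
  rec <- make_record(1000, t0 = night0)
  rec$temp_c <- c(rep(27.5, 200), rep(28.5, 800))
  tat <- compute_tat(rec, "night")
  expect_identical(tat$bin, c(27, 28))
  expect_equal(tat$fraction, c(0.2, 0.8), tolerance = 1e-12)
})

test_that("surface sensor noise is clipped but real negatives are refused", {
  rec <- make_record(10, depth = -0.5)
  tad <- compute_tad(rec)
  expect_identical(tad$bin, 0)
  bad <- make_record(10, depth = -2)
  expect_error(compute_tad(bad), "-1 m")
})

test_that("the pseudo-track passes exactly through every attached fix", {
  fx <- tibble::tibble(time = t0 + c(0, 600, 1200, 1800),
                       x = c(0, 400, 300, 900),
                       y = c(0, 100, 600, 650))
  rec <- make_record(1801, t0 = t0)
  trk <- interpolate_track(fx, rec)
  at_fix <- trk[trk$time %in% fx$time, ]
  expect_equal(at_fix$x, fx$x, tolerance = 1e-9)
  expect_equal(at_fix$y, fx$y, tolerance = 1e-9)
  expect_identical(nrow(trk), 1801L)
})

test_that("two fixes give a straight constant-speed path", {
  fx <- tibble::tibble(time = t0 + c(0, 1000), x = c(0, 500), y = c(0, 1000))
  rec <- make_record(1001, t0 = t0)
  trk <- interpolate_track(fx, rec)
  expect_equal(trk$x, seq(0, 500, length.out = 1001), tolerance = 1e-9)
  step <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
  expect_lt(diff(range(step)), 1e-9)
})

test_that("subsampled smooth paths are recovered within a curvature bound", {
  # known smooth path: gentle sinusoid, fixes every 30 min
  tt <- 0:7200
  px <- 0.5 * tt
  py <- 800 * sin(tt / 3000)
  fix_idx <- seq(1, 7201, by = 1800)
  fx <- tibble::tibble(time = t0 + tt[fix_idx], x = px[fix_idx], y = py[fix_idx])
  rec <- make_record(7201, t0 = t0)
  trk <- interpolate_track(fx, rec)
  err <- sqrt((trk$x - px)^2 + (trk$y - py)^2)
  # curvature kappa ~ 800/3000^2; error bound ~ kappa * (dt*speed)^2
  expect_lt(max(err), 800 / 3000^2 * 1800^2)
})

test_that("redundant collinear fixes leave a straight path unchanged", {
  fx <- tibble::tibble(time = t0 + c(0, 1800, 3600), x = c(0, 900, 1800),
                       y = c(0, 450, 900))
  rec <- make_record(3601, t0 = t0)
  base <- interpolate_track(fx[c(1, 3), ], rec)
  with_mid <- interpolate_track(fx, rec)
  dev <- sqrt((base$x - with_mid$x)^2 + (base$y - with_mid$y)^2)
  expect_lt(max(dev), 1)
})

test_that("insufficient or disordered fixes are rejected", {
  rec <- make_record(100, t0 = t0)
  one <- tibble::tibble(time = t0 + 10, x = 0, y = 0)
  expect_error(interpolate_track(one, rec), "Insufficient fixes")
  dup <- tibble::tibble(time = t0 + c(10, 10), x = c(0, 1), y = c(0, 1))
  expect_error(interpolate_track(dup, rec), "Insufficient fixes")
})

test_that("detached fixes are excluded from interpolation", {
  fx <- tibble::tibble(time = t0 + c(0, 600, 1200),
                       x = c(0, 300, 9999), y = c(0, 300, 9999),
                       attached = c(TRUE, TRUE, FALSE))
  rec <- make_record(1201, t0 = t0)
  trk <- interpolate_track(fx, rec)
  expect_identical(nrow(trk), 601L)   # only up to the last attached fix
  expect_lt(max(trk$x), 301)
})
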