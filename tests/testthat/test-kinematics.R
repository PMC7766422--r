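test_that("gps traces validate time, speed and flag sampling gaps", {
  expect_error(gps_trace(c(0, 0.1, 0.1), c(1, 1, 1)), "increasing")
  expect_error(gps_trace(c(0, 0.1), c(1, -1)), "non-negative")
  g <- gps_trace(c(0, 0.1, 0.2, 0.6), rep(1, 4))
  expect_identical(g$gap, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("csv round trip preserves a trace", {
  g <- sim_noisy()$gps[1:50, ]
  class(g) <- class(gps_trace(1, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gps_csv(g, path)
  g2 <- read_gps_csv(path)
  expect_equal(g2$v, g$v)
  expect_equal(g2$hdop, g$hdop)
})

test_that("nmea round trip preserves speed, position and fix quality", {
  g <- sim_noisy()$gps[1:40, ]
  class(g) <- class(gps_trace(1, 1))
  path <- withr::local_tempfile(fileext = ".nmea")
  write_nmea(g, path)
  g2 <- read_nmea(path)
  expect_equal(nrow(g2), nrow(g))
  expect_equal(g2$v, g$v, tolerance = 1e-3)
  expect_equal(g2$lat, g$lat, tolerance = 1e-6)
  expect_equal(g2$lon, g$lon, tolerance = 1e-6)
  expect_equal(g2$nsat, g$nsat)
  # corrupt one checksum: the sentence is dropped with a warning
  lines <- readLines(path)
  substr(lines[3], nchar(lines[3]) - 1, nchar(lines[3])) <- "00"
  writeLines(lines, path)
  expect_warning(g3 <- read_nmea(path), "checksum")
})

test_that("synchronisation starts the clock at first movement", {
  g <- gps_trace(seq(0, 0.5, 0.1), c(0, 0, 1.2, 1.3, 1.4, 1.5))
  s <- sync_to_first_movement(g)
  expect_equal(s$v[1L], 1.2)
  expect_equal(s$t[1L], 0)
  g2 <- gps_trace(seq(5, 5.3, 0.1), c(1, 1, 1, 1))
  s2 <- sync_to_first_movement(g2)
  expect_equal(s2$t[1L], 0)
  expect_equal(s2$v, g2$v)
  expect_error(sync_to_first_movement(gps_trace(1:3, rep(0, 3))),
               "no movement")
})

test_that("pairwise smoothing halves the rate and conserves displacement", {
  g <- gps_trace(seq(0, 5.9, 0.1), rep(3, 60))
  ks <- smooth_speed(g)
  expect_true(all(ks$v_s == 3))
  expect_equal(1 / median(diff(ks$t)), 5, tolerance = 1e-6)
  # alternating 2/4 m/s collapses to constant 3
  g2 <- gps_trace(seq(0, 5.9, 0.1), rep(c(2, 4), 30))
  expect_true(all(smooth_speed(g2)$v_s == 3))
  # 60 s at 2.86 m/s covers 171.6 m before and after
  g3 <- gps_trace(seq(0, 59.9, 0.1), rep(2.86, 600))
  ks3 <- smooth_speed(g3)
  expect_equal(sum(g3$v) * 0.1, 171.6, tolerance = 1e-9)
  expect_equal(sum(ks3$v_s) * 0.2, 171.6, tolerance = 1e-9)
  expect_error(smooth_speed(gps_trace(1, 1)), "2 samples")
})

test_that("displacement is conserved through smoothing on the circuit", {
  g <- sim_clean()$gps
  ks <- smooth_speed(g)
  d10 <- sum(g$v) * 0.1
  d5 <- sum(ks$v_s[!ks$flag_partial]) * 0.2 +
    sum(ks$v_s[ks$flag_partial]) * 0.1
  expect_equal(d5 / d10, 1, tolerance = 1e-3)
})

test_that("acceleration differencing matches analytic derivatives", {
  t <- seq(0, 59.9, 0.1)
  ks <- smooth_speed(gps_trace(t, rep(3, length(t))))
  ks <- add_acceleration(ks)
  expect_true(all(abs(ks$a) < 1e-9))
  # linear ramp 0 -> 5 over 5 s: interior slope 1.0
  t2 <- seq(0, 5, 0.1)
  ks2 <- add_acceleration(smooth_speed(gps_trace(t2, t2)))
  interior <- ks2$a[3:(nrow(ks2) - 3)]
  expect_true(all(abs(interior - 1) < 1e-9))
  # smooth sinusoidal speed: derivative matches cos within one window of dv
  t3 <- seq(0, 30, 0.1)
  ks3 <- add_acceleration(smooth_speed(gps_trace(t3, 3 + sin(t3))))
  a_true <- cos(ks3$t)
  expect_lt(max(abs(ks3$a - a_true)[5:(nrow(ks3) - 5)]), 0.1)
  # step change: |a| peaks at delta v / window
  v4 <- c(rep(2, 50), rep(4, 50))
  ks4 <- add_acceleration(smooth_speed(gps_trace(seq(0, 9.9, 0.1), v4)),
                          window_s = 0.4)
  expect_equal(max(ks4$a, na.rm = TRUE), 2 / 0.4, tolerance = 0.26)
  expect_error(add_acceleration(ks2, window_s = 0.05), "spacing")
})

test_that("artefact accelerations are flagged and withheld", {
  v <- c(rep(0, 10), rep(30, 10))   # 30 m/s jump: es far beyond 4
  ks <- add_acceleration(smooth_speed(gps_trace(seq(0, 1.9, 0.1), v)))
  expect_true(any(ks$flag_artefact))
  expect_true(all(is.na(ks$a[ks$flag_artefact])))
})

test_that("heading follows bearings and flags stationary samples", {
  # due north at ~0.0001 deg/sample
  lat <- 43 + seq(0, 0.001, length.out = 20)
  g <- gps_trace(seq(0, 1.9, 0.1), rep(5, 20), lat = lat, lon = rep(11, 20))
  h <- add_heading(smooth_speed(g))
  expect_true(all(abs(h$heading) < 1)) # north
  # right-angle corner: heading change of 90 degrees
  n <- 10
  lat2 <- c(43 + seq(0, 9e-4, length.out = n), rep(43 + 9e-4, n))
  lon2 <- c(rep(11, n), 11 + seq(0, 9e-4, length.out = n) / cos(43 * pi / 180))
  g2 <- gps_trace(seq(0, 2 * n / 10 - 0.1, 0.1), rep(5, 2 * n),
                  lat = lat2, lon = lon2)
  h2 <- add_heading(smooth_speed(g2))
  hh <- h2$heading[!is.na(h2$heading)]
  expect_equal(min(hh), 0, tolerance = 2)
  expect_equal(max(hh), 90, tolerance = 2)
  # stationary cluster: undefined heading
  g3 <- gps_trace(seq(0, 0.9, 0.1), rep(0.1, 10),
                  lat = rep(43, 10), lon = rep(11, 10))
  h3 <- add_heading(smooth_speed(g3))
  expect_true(all(h3$flag_heading_undefined))
  expect_error(add_heading(smooth_speed(gps_trace(1:4, rep(1, 4)))),
               "speed-only")
})

test_that("quality filter interpolates isolated bad fixes, drops long runs", {
  n <- 100
  g <- gps_trace(seq(0, 9.9, 0.1), rep(2, n), hdop = rep(1, n),
                 nsat = rep(9, n))
  gq <- quality_filter(g)
  rep1 <- attr(gq, "qc_report")
  expect_equal(rep1$n_interpolated, 0L)
  expect_equal(rep1$n_dropped, 0L)
  # one bad fix: linearly interpolated
  hd <- rep(1, n); hd[50] <- 5
  g2 <- gps_trace(seq(0, 9.9, 0.1), c(rep(2, 49), 99, rep(2, 50)), hdop = hd)
  gq2 <- quality_filter(g2)
  expect_equal(attr(gq2, "qc_report")$n_interpolated, 1L)
  expect_equal(gq2$v[50], 2, tolerance = 1e-9)
  # a 2 s dropout is dropped, leaving a flagged gap
  hd3 <- rep(1, n); hd3[40:59] <- 8
  g3 <- gps_trace(seq(0, 9.9, 0.1), rep(2, n), hdop = hd3)
  gq3 <- quality_filter(g3)
  expect_equal(attr(gq3, "qc_report")$n_dropped, 20L)
  expect_true(any(gq3$gap))
  expect_warning(quality_filter(gps_trace(1:3, rep(1, 3))), "QC fields")
})

test_that("the processing pipeline is deterministic", {
  g <- sim_noisy()$gps
  k1 <- process_gps(g)
  k2 <- process_gps(g)
  expect_identical(k1$power, k2$power)
})
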