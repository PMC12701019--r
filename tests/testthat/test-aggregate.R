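fake_meas <- function(heights, well = "w1", t = 0, method = "reflection") {
  tibble::tibble(
    well_id = well, position = seq_along(heights), time_min = t,
    method = method, asl_um = heights, cell_um = 15, z2_offset_um = 0,
    flags = ""
  )
}

test_that("serpentine plans traverse the grid boustrophedon", {
  p <- serpentine_positions(3, 5)
  expect_equal(nrow(p), 15)
  expect_equal(p$col[p$row == 1], 1:5)
  expect_equal(p$col[p$row == 2], 5:1)
  expect_equal(p$col[p$row == 3], 1:5)
  expect_false(any(duplicated(p[, c("row", "col")])))
  # positions confined to the central fraction of the field
  expect_true(all(p$u >= 0.2 & p$u <= 0.8))

  p1 <- serpentine_positions(1, 7)
  expect_equal(p1$col, 1:7)

  p42 <- serpentine_positions(4, 2)
  expect_equal(nrow(p42), 8)
  expect_false(any(duplicated(p42[, c("row", "col")])))

  expect_error(serpentine_positions(0, 5), ">= 1")
})

test_that("well summary matches hand arithmetic", {
  s <- summarize_well(fake_meas(c(4, 6, 8)))
  expect_equal(s$mean_um, 6)
  expect_equal(s$sd_um, 2)
  expect_equal(s$sem_um, 2 / sqrt(3), tolerance = 1e-9)
  expect_equal(s$cv_pct, 100 * 2 / 6, tolerance = 1e-9)

  s0 <- summarize_well(fake_meas(rep(5.5, 10)))
  expect_equal(s0$sd_um, 0)
  expect_equal(s0$cv_pct, 0)
})

test_that("well summary is permutation-invariant and excludes flagged rows", {
  h <- c(3.2, 4.1, 5.9, 7.3, 6.6)
  s1 <- summarize_well(fake_meas(h))
  s2 <- summarize_well(fake_meas(rev(h)))
  expect_equal(s1$mean_um, s2$mean_um)
  expect_equal(s1$sd_um, s2$sd_um)

  m <- fake_meas(c(h, 99))
  m$flags[6] <- "insufficient_peaks"
  m$asl_um[6] <- NA
  s3 <- summarize_well(m)
  expect_equal(s3$n_positions, 5)
  expect_equal(s3$n_flagged, 1)
  expect_equal(s3$mean_um, mean(h))

  # clamped zeros are kept: dropping them would bias the mean upward
  mc <- fake_meas(c(2, 0, 4))
  mc$flags[2] <- "negative_clamped"
  expect_equal(summarize_well(mc)$mean_um, 2)

  expect_error(summarize_well(fake_meas(5)), "insufficient")
})

test_that("CV is invariant to rescaling all heights", {
  h <- c(4, 5, 6, 7)
  cv1 <- summarize_well(fake_meas(h))$cv_pct
  cv2 <- summarize_well(fake_meas(h * 13))$cv_pct
  expect_equal(cv1, cv2, tolerance = 1e-12)
})

test_that("phantom well mean is recovered within 0.3 um at default noise", {
  cfg <- phantom_config(asl_height = 8.8, noise_gaussian_sd = 0.05, tilt = 1)
  scan <- render_scan(cfg, seed = 12)
  m <- measure_scan(scan, method = "reflection", well_id = "ph1")
  s <- summarize_well(m)
  expect_equal(s$n_positions, 15)
  expect_equal(s$mean_um, 8.8, tolerance = 0.3)
})

test_that("subsampling at the full size reproduces the full summary", {
  m <- fake_meas(c(4.2, 5.1, 6.7, 7.4, 8.9, 5.5))
  full <- summarize_well(m)
  st <- subsample_stability(m, sizes = 6, n_reps = 5, seed = 1)
  expect_equal(st$mean_of_means_um, full$mean_um, tolerance = 1e-12)
  expect_equal(st$mean_sd_um, full$sd_um, tolerance = 1e-12)
  expect_equal(st$mean_cv_pct, full$cv_pct, tolerance = 1e-12)
})

test_that("subsampling is seeded-reproducible and validates sizes", {
  m <- fake_meas(rnorm(20, 8, 1))
  t1 <- subsample_stability(m, sizes = c(10, 15), n_reps = 50, seed = 99)
  t2 <- subsample_stability(m, sizes = c(10, 15), n_reps = 50, seed = 99)
  expect_identical(t1, t2)
  expect_error(subsample_stability(m, sizes = 25, n_reps = 5, seed = 1),
               "exceeds")
})

test_that("timecourse sorts by time and rejects duplicate time points", {
  s <- dplyr::bind_rows(
    summarize_well(fake_meas(c(6, 7, 8), t = 120)),
    summarize_well(fake_meas(c(9, 10, 11), t = 0)),
    summarize_well(fake_meas(c(5, 6, 7), t = 360))
  )
  tc <- timecourse(s)
  expect_equal(tc$time_min, c(0, 120, 360))
  expect_error(timecourse(dplyr::bind_rows(tc, tc[1, ])), "duplicate")

  single <- summarize_well(fake_meas(c(6, 7, 8)))
  expect_equal(nrow(timecourse(single)), 1)
})

test_that("a volume-challenge series relaxes as rendered and measured", {
  cfg <- phantom_config(noise_gaussian_sd = 0.05, n_z = 400)
  times <- c(0, 120, 360, 1440)
  scans <- volume_challenge_series(cfg, initial_height = 20,
                                   steady_height = 6, tau = 60,
                                   times = times, seed = 31)
  summaries <- dplyr::bind_rows(lapply(seq_along(scans), function(i) {
    summarize_well(measure_scan(scans[[i]], method = "reflection",
                                well_id = "vc", time_min = times[i]))
  }))
  tc <- timecourse(summaries)
  expected <- 6 + 14 * exp(-times / 60)
  expect_equal(tc$mean_um, expected, tolerance = 0.05)
})
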