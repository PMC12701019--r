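test_that("extract_profile averages lateral columns as specified", {
  img <- matrix(7, nrow = 20, ncol = 10)
  p <- extract_profile(img, 5, width = 3, z_spacing = 0.2)
  expect_equal(p$intensities, rep(7, 20))

  img2 <- matrix(rnorm(200), nrow = 20)
  p1 <- extract_profile(img2, 4, width = 1, z_spacing = 0.2)
  expect_equal(p1$intensities, img2[, 4])

  img3 <- matrix(rep(c(1, 2, 3), each = 20), nrow = 20)
  p3 <- extract_profile(img3, 2, width = 3, z_spacing = 0.2)
  expect_equal(p3$intensities, rep(2, 20))

  expect_error(extract_profile(img, 1, width = 3, z_spacing = 0.2),
               "outside")
  expect_error(extract_profile(img, 10, width = 3, z_spacing = 0.2),
               "outside")
})

test_that("Gaussian peak fit recovers sub-pixel centers, baseline-invariant", {
  p0 <- gaussian_profile(10.30, 0.8, 1)
  f0 <- fit_gaussian_peak(p0, 10.4)
  expect_true(f0$ok)
  expect_equal(f0$center, 10.30, tolerance = 1e-3)

  p5 <- gaussian_profile(10.30, 0.8, 1, baseline = 5)
  f5 <- fit_gaussian_peak(p5, 10.4)
  expect_equal(f5$center, f0$center, tolerance = 1e-6)
  expect_equal(f5$baseline, 5, tolerance = 1e-3)

  # intensity rescaling leaves the center unchanged
  p2 <- p0; p2$intensities <- p0$intensities * 37
  f2 <- fit_gaussian_peak(p2, 10.4)
  expect_equal(f2$center, f0$center, tolerance = 1e-6)
})

test_that("fitted centers stay accurate under detector noise", {
  # Monte-Carlo: noise sd 5% of amplitude, mean |center error| < 0.05 um
  set.seed(11)
  errs <- replicate(200, {
    p <- gaussian_profile(10.30, 0.8, 1)
    p$intensities <- p$intensities + rnorm(length(p$intensities), 0, 0.05)
    abs(fit_gaussian_peak(p, 10.30)$center - 10.30)
  })
  expect_lt(mean(errs), 0.05)
})

test_that("reflection peak detection honours the prominence threshold", {
  p3 <- gaussian_profile(c(2, 8, 20), c(0.7, 0.7, 0.7), c(0.4, 0.25, 0.8))
  peaks <- detect_reflection_peaks(p3)
  expect_length(peaks, 3)
  centers <- vapply(peaks, `[[`, numeric(1), "center")
  expect_equal(centers, c(2, 8, 20), tolerance = 0.2)

  # a bump below 10% of the profile max must not add a fourth peak
  p4 <- gaussian_profile(c(2, 8, 14, 20), rep(0.7, 4), c(0.4, 0.25, 0.05, 0.8))
  expect_length(detect_reflection_peaks(p4), 3)

  p2 <- gaussian_profile(c(2, 20), c(0.7, 0.7), c(0.4, 0.8))
  expect_error(detect_reflection_peaks(p2),
               class = "asl_insufficient_peaks")
})

test_that("interface classification keeps the 3 most prominent, depth-ordered", {
  p3 <- gaussian_profile(c(3, 11, 26), rep(0.7, 3), c(0.4, 0.25, 0.8))
  ifc <- classify_interfaces(detect_reflection_peaks(p3))
  expect_equal(c(ifc$z1, ifc$z2, ifc$z3), c(3, 11, 26), tolerance = 0.2)

  # a spurious fourth peak of least prominence is dropped
  p4 <- gaussian_profile(c(3, 11, 17, 26), rep(0.7, 4),
                         c(0.4, 0.25, 0.15, 0.8))
  ifc4 <- classify_interfaces(detect_reflection_peaks(p4))
  expect_equal(c(ifc4$z1, ifc4$z2, ifc4$z3), c(3, 11, 26), tolerance = 0.2)

  expect_error(classify_interfaces(list()), "3 peaks")
})

test_that("classified interfaces on a phantom equal ground truth", {
  for (tilt in c(0, 2)) {
    cfg <- quiet_cfg(asl = 8.8, tilt = tilt)
    scan <- render_scan(cfg, seed = 2)
    x <- 80
    prof <- extract_profile(scan, x, channel = "reflection")
    ifc <- classify_interfaces(detect_reflection_peaks(prof))
    off <- mean(scan$truth$position_offsets[78:82])
    expect_equal(ifc$z1, scan$truth$z1 + off, tolerance = cfg$z_spacing)
    expect_equal(ifc$z2, scan$truth$z2 + off, tolerance = cfg$z_spacing)
    expect_equal(ifc$z3, scan$truth$z3 + off, tolerance = cfg$z_spacing)
  }
})

test_that("half-maximum bounds: triangle, rectangle and blurred step", {
  # triangle rising 6 -> 10, falling 10 -> 14, sampled at 1 um
  z <- 0:20
  tri <- pmax(0, 100 * (1 - abs(z - 10) / 4))
  ptri <- aslheight:::new_z_profile(tri, 1, "rhodamine")
  btri <- half_max_bounds(ptri)
  expect_equal(c(btri$z_lower, btri$z_upper), c(8, 12))

  zz <- seq(0, 20, by = 0.2)
  rect <- as.numeric(zz >= 5 & zz <= 12)
  prect <- aslheight:::new_z_profile(rect, 0.2, "calcein")
  brect <- half_max_bounds(prect)
  expect_equal(c(brect$z_lower, brect$z_upper), c(5, 12), tolerance = 0.11)

  blur <- pnorm((zz - 5) / 0.7) - pnorm((zz - 12) / 0.7)
  pblur <- aslheight:::new_z_profile(blur, 0.2, "calcein")
  bblur <- half_max_bounds(pblur)
  expect_equal(bblur$z_lower, 5, tolerance = 0.05)
  expect_equal(bblur$z_upper, 12, tolerance = 0.05)
})

test_that("half-maximum bounds are invariant to scale and offset", {
  zz <- seq(0, 20, by = 0.2)
  y <- pnorm((zz - 6) / 0.7) - pnorm((zz - 13) / 0.7)
  b0 <- half_max_bounds(aslheight:::new_z_profile(y, 0.2, "calcein"))
  for (k in c(0.5, 3, 100)) for (c0 in c(0, 0.2, 10)) {
    b <- half_max_bounds(aslheight:::new_z_profile(k * y + c0, 0.2, "calcein"))
    expect_equal(b$z_lower, b0$z_lower, tolerance = 1e-9)
    expect_equal(b$z_upper, b0$z_upper, tolerance = 1e-9)
  }
})

test_that("a band running off the stack is flagged, not silently bounded", {
  zz <- seq(0, 20, by = 0.2)
  y <- pnorm((zz - 18) / 0.7) # rises near the end, never comes back down
  b <- half_max_bounds(aslheight:::new_z_profile(y, 0.2, "rhodamine"))
  expect_false(b$ok)
  expect_identical(b$flag, "boundary_failure")
})
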