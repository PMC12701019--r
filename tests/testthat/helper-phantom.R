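# Shared fixtures: small phantoms and synthetic profiles built in code.

quiet_cfg <- function(asl = 7, noise = 0, tilt = 0, ...) {
  phantom_config(asl_height = asl, noise_gaussian_sd = noise, tilt = tilt, ...)
}

# Profile of Gaussian bumps (centers/sigmas/amps in um) on a z grid.
gaussian_profile <- function(centers, sigmas, amps, baseline = 0,
                             z_max = 30, z_spacing = 0.2,
                             channel = "reflection") {
  z <- seq(0, z_max, by = z_spacing)
  y <- baseline + Reduce(`+`, Map(function(c0, s0, a0) {
    a0 * exp(-(z - c0)^2 / (2 * s0^2))
  }, centers, sigmas, amps))
  aslheight:::new_z_profile(y, z_spacing, channel)
}

# local maxima of a trace, independent of the package's detector;
# equal-valued flat tops (quantization ties) collapse to their midpoint
strict_maxima <- function(y) {
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  keep <- vapply(seq_len(nr), function(i) {
    (i == 1L || r$values[i - 1] < r$values[i]) &&
      (i == nr || r$values[i + 1] < r$values[i])
  }, logical(1))
  as.integer(floor((starts[keep] + ends[keep]) / 2))
}
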