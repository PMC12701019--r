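#' Fresnel reflectance at normal incidence
#'
#' Fraction of light intensity reflected at a planar interface between two
#' media of refractive index `n1` and `n2`, for normal incidence:
#' \deqn{R = \left(\frac{n_1 - n_2}{n_1 + n_2}\right)^2}
#' This is the amplitude model used for the three reflection peaks of the
#' phantom generator (medium to transwell, transwell to cell layer, ASL to
#' air).
#'
#' @param n1,n2 Refractive indices (dimensionless, must be >= 1).
#' @return Reflectance as a fraction in `[0, 1)`. Symmetric in its arguments.
#' @examples
#' fresnel_reflectance(1.34, 1.00) # ASL -> air, about 0.021
#' @export
fresnel_reflectance <- function(n1, n2) {
  if (any(!is.finite(c(n1, n2))) || any(c(n1, n2) < 1)) {
    stop("refractive indices must be finite and >= 1.0", call. = FALSE)
  }
  ((n1 - n2) / (n1 + n2))^2
}

default_refractive_indices <- function() {
  c(medium = 1.33, transwell = 1.58, cell = 1.37, asl = 1.34, air = 1.00)
}

#' Phantom configuration
#'
#' Geometry and optics of a synthetic XZ confocal scan of an air-liquid
#' interface culture. Depth (z) increases from the first stack plane toward
#' the air above the ASL; all depths are in micrometres.
#'
#' @param z_spacing Axial pixel spacing (um/pixel).
#' @param n_z,n_x Stack size in pixels (z planes, lateral columns).
#' @param transwell_top_z Depth of the transwell-to-cell interface (um).
#' @param transwell_thickness Membrane thickness (um); the medium-to-transwell
#'   interface sits at `transwell_top_z - transwell_thickness`.
#' @param cell_height Thickness of the epithelial cell layer (um).
#' @param asl_height Thickness of the airway surface layer (um); zero allowed.
#' @param refractive_indices Named vector with entries `medium`, `transwell`,
#'   `cell`, `asl`, `air`; all >= 1.
#' @param psf_sigma_axial Gaussian sigma of the axial point spread (um).
#' @param noise_gaussian_sd Detector noise standard deviation, as a fraction
#'   of the brightest rendered peak.
#' @param tilt Linear drift of interface depth across the lateral field (um
#'   over the full field width), emulating a non-level insert.
#' @param n_positions Number of measurement positions per well.
#' @param rhodamine Render the apical rhodamine-dextran channel as well?
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(z_spacing = 0.2,
                           n_z = 300,
                           n_x = 160,
                           transwell_top_z = 14,
                           transwell_thickness = 10,
                           cell_height = 15,
                           asl_height = 7,
                           refractive_indices = default_refractive_indices(),
                           psf_sigma_axial = 0.7,
                           noise_gaussian_sd = 0.05,
                           tilt = 0,
                           n_positions = 15,
                           rhodamine = TRUE) {
  cfg <- list(
    z_spacing = z_spacing, n_z = as.integer(n_z), n_x = as.integer(n_x),
    transwell_top_z = transwell_top_z,
    transwell_thickness = transwell_thickness,
    cell_height = cell_height, asl_height = asl_height,
    refractive_indices = refractive_indices,
    psf_sigma_axial = psf_sigma_axial,
    noise_gaussian_sd = noise_gaussian_sd,
    tilt = tilt, n_positions = as.integer(n_positions),
    rhodamine = isTRUE(rhodamine)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot(
    cfg$z_spacing > 0, cfg$n_z >= 8, cfg$n_x >= 1,
    cfg$transwell_thickness >= 0, cfg$cell_height >= 0,
    cfg$asl_height >= 0, cfg$psf_sigma_axial > 0,
    cfg$noise_gaussian_sd >= 0, cfg$n_positions >= 1
  )
  need <- c("medium", "transwell", "cell", "asl", "air")
  if (!all(need %in% names(cfg$refractive_indices))) {
    stop("refractive_indices must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(cfg$refractive_indices < 1)) {
    stop("refractive indices must be >= 1.0", call. = FALSE)
  }
  if (cfg$transwell_top_z < cfg$transwell_thickness) {
    stop("medium->transwell interface would lie above the first plane",
         call. = FALSE)
  }
  depth_needed <- cfg$transwell_top_z + cfg$cell_height + cfg$asl_height +
    3 * cfg$psf_sigma_axial
  if (cfg$n_z * cfg$z_spacing <= depth_needed) {
    stop(sprintf(
      "stack too shallow for geometry: need > %.1f um, have %.1f um",
      depth_needed, cfg$n_z * cfg$z_spacing), call. = FALSE)
  }
  invisible(cfg)
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a synthetic XZ scan
#'
#' Forward model of the optical setup: three reflection lines at the
#' refractive-index interfaces with normal-incidence Fresnel amplitudes,
#' blurred axially by a Gaussian point spread; a calcein plateau over the
#' cell layer and (optionally) a rhodamine plateau over the ASL, blurred
#' identically; additive Gaussian detector noise; linear lateral tilt.
#' Intensities are clamped to `[0, 1]` and quantized to 16 bits, emulating
#' detector digitization (and making TIFF round trips exact).
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; identical seeds give bit-identical scans.
#' @return An `asl_scan`: list with `reflection`, `calcein`, optionally
#'   `rhodamine` (each an `n_z` x `n_x` matrix, rows = depth), `z_spacing`,
#'   and `truth` (a `phantom_truth`: interface depths at field centre,
#'   per-column depth offsets, true cell and ASL heights).
#' @export
render_scan <- function(config, seed = NULL) {
  validate_phantom_config(config)
  with_seed(seed, render_scan_impl(config))
}

render_scan_impl <- function(cfg) {
  z <- (seq_len(cfg$n_z) - 1) * cfg$z_spacing
  ri <- cfg$refractive_indices
  z1 <- cfg$transwell_top_z - cfg$transwell_thickness
  z2 <- cfg$transwell_top_z
  z3 <- z2 + cfg$cell_height + cfg$asl_height

  amp <- c(
    fresnel_reflectance(ri[["medium"]], ri[["transwell"]]),
    fresnel_reflectance(ri[["transwell"]], ri[["cell"]]),
    fresnel_reflectance(ri[["asl"]], ri[["air"]])
  )
  # brightest peak rendered at 0.8 full scale; noise headroom to 1.0
  scale <- 0.8 / max(amp)
  sig <- cfg$psf_sigma_axial

  if (cfg$n_x > 1) {
    offsets <- cfg$tilt * ((seq_len(cfg$n_x) - 1) / (cfg$n_x - 1) - 0.5)
  } else {
    offsets <- 0
  }

  render_channel <- function(profile_fun) {
    img <- vapply(offsets, function(off) profile_fun(z - off), numeric(cfg$n_z))
    if (cfg$noise_gaussian_sd > 0) {
      img <- img + matrix(
        stats::rnorm(length(img), 0, cfg$noise_gaussian_sd * 0.8),
        nrow = cfg$n_z)
    }
    quantize16(img)
  }

  reflection <- render_channel(function(zz) {
    scale * (amp[1] * exp(-(zz - z1)^2 / (2 * sig^2)) +
             amp[2] * exp(-(zz - z2)^2 / (2 * sig^2)) +
             amp[3] * exp(-(zz - z3)^2 / (2 * sig^2)))
  })
  calcein <- render_channel(function(zz) {
    0.8 * blurred_band(zz, z2, z2 + cfg$cell_height, sig)
  })
  rhodamine <- NULL
  if (cfg$rhodamine) {
    rhodamine <- render_channel(function(zz) {
      0.8 * blurred_band(zz, z2 + cfg$cell_height, z3, sig)
    })
  }

  truth <- structure(list(
    z1 = z1, z2 = z2, z3 = z3,
    true_cell_height = cfg$cell_height,
    true_asl_height = cfg$asl_height,
    position_offsets = offsets
  ), class = "phantom_truth")

  structure(list(
    reflection = reflection, calcein = calcein, rhodamine = rhodamine,
    z_spacing = cfg$z_spacing, truth = truth, config = cfg
  ), class = "asl_scan")
}

# Ideal rectangular band [a, b] convolved with a Gaussian of sigma `sig`:
# crosses half its plateau exactly at a and b.
blurred_band <- function(z, a, b, sig) {
  stats::pnorm((z - a) / sig) - stats::pnorm((z - b) / sig)
}

quantize16 <- function(img) {
  round(pmin(pmax(img, 0), 1) * 65535) / 65535
}

#' @export
print.asl_scan <- function(x, ...) {
  ch <- c("reflection", "calcein", if (!is.null(x$rhodamine)) "rhodamine")
  cat(sprintf("<asl_scan> %d z x %d x pixels, z-step %.3g um, channels: %s\n",
              nrow(x$reflection), ncol(x$reflection), x$z_spacing,
              paste(ch, collapse = ", ")))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: z1=%.2f z2=%.2f z3=%.2f, cell %.2f um, ASL %.2f um\n",
                x$truth$z1, x$truth$z2, x$truth$z3,
                x$truth$true_cell_height, x$truth$true_asl_height))
  }
  invisible(x)
}

#' Simulate ASL relaxation after an apical volume challenge
#'
#' Renders one scan per requested time point with the true ASL height
#' following a single-exponential return to steady state,
#' `h(t) = steady + (initial - steady) * exp(-t / tau)` — a simulation
#' convention for the reabsorption of an apical liquid bolus.
#'
#' @param config Base [phantom_config()]; its `asl_height` is overridden.
#' @param initial_height ASL height immediately after the challenge (um).
#' @param steady_height Steady-state ASL height (um).
#' @param tau Relaxation time constant (minutes), > 0.
#' @param times Time points in minutes, all >= 0.
#' @param seed Base seed; scan at time index `i` uses `seed + i - 1`.
#' @return List of `asl_scan`s, one per time point; each carries `time_min`.
#' @export
volume_challenge_series <- function(config, initial_height, steady_height,
                                    tau, times, seed = NULL) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  heights <- steady_height + (initial_height - steady_height) * exp(-times / tau)
  scans <- vector("list", length(times))
  for (i in seq_along(times)) {
    cfg_t <- config
    cfg_t$asl_height <- heights[i]
    scan <- render_scan(cfg_t, seed = if (is.null(seed)) NULL else seed + i - 1)
    scan$time_min <- times[i]
    scans[[i]] <- scan
  }
  scans
}
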