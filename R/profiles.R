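#' Extract an axial line profile from an XZ image
#'
#' Averages `width` adjacent lateral columns centred at `x_index` (1-based),
#' giving one intensity-versus-depth trace. Averaging a few columns reduces
#' detector noise without blurring lateral tilt appreciably.
#'
#' @param image `n_z` x `n_x` intensity matrix (rows = depth), or an
#'   `asl_scan` together with `channel`.
#' @param x_index Lateral column at the window centre (1-based).
#' @param width Number of columns to average (odd recommended; default 5).
#' @param z_spacing Axial pixel spacing in um (taken from the scan if an
#'   `asl_scan` is supplied).
#' @param channel One of `"reflection"`, `"calcein"`, `"rhodamine"`.
#' @return A `z_profile`: list with `intensities`, `z` (depths, um),
#'   `z_spacing`, `channel`, `x_position`.
#' @export
extract_profile <- function(image, x_index, width = 5,
                            z_spacing = NULL,
                            channel = c("reflection", "calcein", "rhodamine")) {
  channel <- match.arg(channel)
  if (inherits(image, "asl_scan")) {
    mat <- image[[channel]]
    if (is.null(mat)) {
      stop(sprintf("scan has no '%s' channel", channel), call. = FALSE)
    }
    if (is.null(z_spacing)) z_spacing <- image$z_spacing
  } else {
    mat <- image
  }
  if (is.null(z_spacing) || z_spacing <= 0) {
    stop("z_spacing must be supplied and > 0", call. = FALSE)
  }
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  half <- (width - 1) %/% 2
  lo <- x_index - half
  hi <- lo + width - 1
  if (lo < 1 || hi > ncol(mat)) {
    stop(sprintf("profile window [%d, %d] outside image (1..%d columns)",
                 lo, hi, ncol(mat)), call. = FALSE)
  }
  ints <- rowMeans(mat[, lo:hi, drop = FALSE])
  new_z_profile(ints, z_spacing, channel, x_index)
}

new_z_profile <- function(intensities, z_spacing, channel, x_position = NA) {
  stopifnot(length(intensities) >= 8, z_spacing > 0)
  structure(list(
    intensities = as.numeric(intensities),
    z = (seq_along(intensities) - 1) * z_spacing,
    z_spacing = z_spacing,
    channel = channel,
    x_position = x_position
  ), class = "z_profile")
}

#' Fit a Gaussian peak to a window of an axial profile
#'
#' Least-squares fit of `baseline + amplitude * exp(-(z - center)^2 /
#' (2 sigma^2))` over the samples within `window_halfwidth` of
#' `window_center`, by Levenberg-Marquardt. Gives sub-pixel peak positions.
#'
#' @param profile A `z_profile`.
#' @param window_center Window centre (um).
#' @param window_halfwidth Window half width (um, default 2).
#' @param r2_threshold Fits with R-squared below this are flagged (default 0.9).
#' @return A `peak_fit`: `center`, `sigma`, `amplitude`, `baseline`,
#'   `r_squared` (all um / intensity units), `ok` (passed QC) and `flag`
#'   (`NA` or a failure reason). A failed or non-convergent fit is returned
#'   flagged, never as a silent `NA` height downstream.
#' @export
fit_gaussian_peak <- function(profile, window_center, window_halfwidth = 2,
                              r2_threshold = 0.9) {
  stopifnot(inherits(profile, "z_profile"))
  inside <- abs(profile$z - window_center) <= window_halfwidth
  if (sum(inside) < 5) {
    stop("fit window must contain at least 5 samples", call. = FALSE)
  }
  z <- profile$z[inside]
  y <- profile$intensities[inside]
  start <- list(
    b0 = min(y),
    a0 = max(y) - min(y),
    c0 = z[which.max(y)],
    s0 = max(profile$z_spacing, window_halfwidth / 4)
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b0 + a0 * exp(-(z - c0)^2 / (2 * s0^2)),
      data = data.frame(z = z, y = y), start = start,
      lower = c(b0 = -Inf, a0 = 0, c0 = min(z), s0 = profile$z_spacing / 10),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_peak_fit(NA, NA, NA, NA, NA, ok = FALSE, flag = "fit_failed"))
  }
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  ok <- is.finite(r2) && r2 >= r2_threshold && cf[["a0"]] > 0
  new_peak_fit(cf[["c0"]], cf[["s0"]], cf[["a0"]], cf[["b0"]], r2,
               ok = ok, flag = if (ok) NA_character_ else "low_r_squared")
}

new_peak_fit <- function(center, sigma, amplitude, baseline, r_squared,
                         ok, flag = NA_character_, prominence = NA_real_) {
  structure(list(
    center = center, sigma = sigma, amplitude = amplitude,
    baseline = baseline, r_squared = r_squared,
    ok = ok, flag = flag, prominence = prominence
  ), class = "peak_fit")
}

# Topographic prominence of local maxima in a numeric trace.
# Equal-valued runs (flat tops from detector quantization) are collapsed to
# a single candidate at the run midpoint. For each maximum: walk out on
# each side to the nearest higher sample (or the trace end); the key saddle
# is the higher of the two interval minima; prominence = height - saddle.
peak_prominences <- function(y) {
  r <- rle(y)
  vals <- r$values
  nr <- length(vals)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- vapply(seq_len(nr), function(i) {
    (i == 1L || vals[i - 1] < vals[i]) && (i == nr || vals[i + 1] < vals[i])
  }, logical(1))
  if (nr == 1L) is_max <- FALSE
  which_max <- which(is_max)
  idx <- as.integer(floor((starts[which_max] + ends[which_max]) / 2))
  prom <- vapply(which_max, function(i) {
    h <- vals[i]
    left <- if (i > 1) {
      j <- i - 1L
      m <- vals[j]
      while (j > 1 && vals[j] <= h) { j <- j - 1L; m <- min(m, vals[j]) }
      m
    } else h
    right <- if (i < nr) {
      j <- i + 1L
      m <- vals[j]
      while (j < nr && vals[j] <= h) { j <- j + 1L; m <- min(m, vals[j]) }
      m
    } else h
    h - max(left, right)
  }, numeric(1))
  list(index = idx, prominence = prom)
}

#' Detect reflection peaks in an axial profile
#'
#' Candidate local maxima whose topographic prominence exceeds
#' `min_prominence` times the profile maximum are each refined by
#' [fit_gaussian_peak()]. A usable reflection profile must yield the three
#' interface peaks (medium-transwell, transwell-cell, ASL-air).
#'
#' @param profile A reflection-channel `z_profile`.
#' @param min_prominence Prominence threshold as a fraction of the profile
#'   maximum (default 0.1).
#' @param window_halfwidth Fit window half width passed on (um).
#' @param r2_threshold Fit QC threshold passed on.
#' @return List of `peak_fit`s sorted by centre depth, each carrying its
#'   detection `prominence`.
#' @section Errors: fewer than 3 candidates raises an error of class
#'   `asl_insufficient_peaks`; callers flag the position and exclude it from
#'   the well mean.
#' @export
detect_reflection_peaks <- function(profile, min_prominence = 0.1,
                                    window_halfwidth = 2,
                                    r2_threshold = 0.9) {
  stopifnot(inherits(profile, "z_profile"))
  y <- profile$intensities
  pk <- peak_prominences(y)
  thr <- min_prominence * max(y)
  keep <- pk$prominence >= thr
  if (sum(keep) < 3) {
    stop(structure(class = c("asl_insufficient_peaks", "error", "condition"),
                   list(message = sprintf(
                     "found %d reflection peaks above prominence %.3g, need 3",
                     sum(keep), thr),
                     call = NULL)))
  }
  idx <- pk$index[keep]
  prom <- pk$prominence[keep]
  fits <- lapply(seq_along(idx), function(i) {
    f <- fit_gaussian_peak(profile, profile$z[idx[i]],
                           window_halfwidth = window_halfwidth,
                           r2_threshold = r2_threshold)
    # fall back to the sample position if the local fit failed, keep flag
    if (!isTRUE(f$ok) && !is.finite(f$center)) f$center <- profile$z[idx[i]]
    f$prominence <- prom[i]
    f
  })
  ord <- order(vapply(fits, `[[`, numeric(1), "center"))
  fits[ord]
}

#' Classify reflection peaks into the three optical interfaces
#'
#' Keeps the three most prominent peaks (ties broken toward smaller depth)
#' and assigns them by ascending depth: z1 medium-to-transwell, z2
#' transwell-to-cell, z3 ASL-to-air.
#'
#' @param peaks List of `peak_fit`s from [detect_reflection_peaks()].
#' @return A `reflection_interfaces`: `z1`, `z2`, `z3` (um) plus the three
#'   component `peak_fit`s.
#' @export
classify_interfaces <- function(peaks) {
  if (length(peaks) < 3) {
    stop("need at least 3 peaks to classify interfaces", call. = FALSE)
  }
  prom <- vapply(peaks, `[[`, numeric(1), "prominence")
  ctr <- vapply(peaks, `[[`, numeric(1), "center")
  keep <- order(-prom, ctr)[1:3]
  keep <- keep[order(ctr[keep])]
  sel <- peaks[keep]
  z <- vapply(sel, `[[`, numeric(1), "center")
  structure(list(
    z1 = z[1], z2 = z[2], z3 = z[3], peaks = sel
  ), class = "reflection_interfaces")
}

#' Half-maximum boundaries of a fluorescence band
#'
#' Locates the edges of a plateau-shaped fluorescence band (calcein cell
#' layer or rhodamine ASL) as the outermost crossings of half the plateau
#' level, by linear interpolation between samples. The baseline is the 5th
#' percentile of the profile; the plateau reference is the median of the
#' baseline-subtracted samples lying in the top decile of the intensity
#' range (robust to a bright rim at the air interface). A blurred step
#' crosses half level at the true edge, so edges are recovered without
#' deconvolution.
#'
#' @param profile A fluorescence-channel `z_profile`.
#' @return A `half_max_bounds`: `z_lower`, `z_upper` (um), `reference_level`
#'   (plateau, baseline subtracted), `baseline`, `ok`, `flag`. If no crossing
#'   exists on one side the result is flagged `"boundary_failure"` with `NA`
#'   bounds.
#' @export
half_max_bounds <- function(profile) {
  stopifnot(inherits(profile, "z_profile"))
  y <- profile$intensities
  z <- profile$z
  baseline <- stats::quantile(y, 0.05, names = FALSE)
  ys <- y - baseline
  top <- max(ys)
  if (top <= 0) {
    return(new_half_max_bounds(NA, NA, NA, baseline,
                               ok = FALSE, flag = "boundary_failure"))
  }
  ref <- stats::median(ys[ys >= 0.9 * top])
  half <- ref / 2
  above <- ys >= half
  if (!any(above)) {
    return(new_half_max_bounds(NA, NA, ref, baseline,
                               ok = FALSE, flag = "boundary_failure"))
  }
  first <- which(above)[1]
  last <- which(above)[length(which(above))]
  cross <- function(i0, i1) {
    # linear interpolation of the half-level crossing between samples i0, i1
    z[i0] + (half - ys[i0]) * (z[i1] - z[i0]) / (ys[i1] - ys[i0])
  }
  ok <- TRUE; flag <- NA_character_
  z_lower <- if (first == 1) { ok <- FALSE; flag <- "boundary_failure"; NA }
             else cross(first - 1L, first)
  z_upper <- if (last == length(ys)) { ok <- FALSE; flag <- "boundary_failure"; NA }
             else cross(last + 1L, last)
  new_half_max_bounds(z_lower, z_upper, ref, baseline, ok = ok, flag = flag)
}

new_half_max_bounds <- function(z_lower, z_upper, reference_level, baseline,
                                ok, flag = NA_character_) {
  structure(list(
    z_lower = z_lower, z_upper = z_upper,
    reference_level = reference_level, baseline = baseline,
    ok = ok, flag = flag
  ), class = "half_max_bounds")
}
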