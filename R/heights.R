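#' Cell-layer height from calcein half-maximum bounds
#'
#' The epithelial cell layer is the width of the basolaterally loaded
#' calcein-AM band between its half-maximum boundaries.
#'
#' @param calcein_bounds A `half_max_bounds` from the calcein channel.
#' @return Height in um (`NA` if the bounds are flagged).
#' @export
cell_height <- function(calcein_bounds) {
  stopifnot(inherits(calcein_bounds, "half_max_bounds"))
  if (!isTRUE(calcein_bounds$ok)) return(NA_real_)
  calcein_bounds$z_upper - calcein_bounds$z_lower
}

#' ASL height by the reflection method
#'
#' Reflection peak separation minus cell-layer thickness: the distance
#' between the transwell-to-cell and ASL-to-air reflection peaks (z3 - z2)
#' minus the calcein half-maximum width. Small negative values (noise) are
#' clamped to 0 and flagged rather than dropped, so well means are not
#' biased upward. The offset between z2 and the calcein lower bound is
#' returned as a QC metric.
#'
#' @param interfaces A `reflection_interfaces`.
#' @param calcein_bounds Calcein-channel `half_max_bounds`.
#' @return List: `asl_um`, `cell_um`, `z2_offset_um` (z2 minus calcein lower
#'   bound), `flags` (character vector, possibly empty).
#' @export
asl_height_reflection <- function(interfaces, calcein_bounds) {
  stopifnot(inherits(interfaces, "reflection_interfaces"))
  ch <- cell_height(calcein_bounds)
  if (!is.finite(ch)) {
    return(list(asl_um = NA_real_, cell_um = NA_real_,
                z2_offset_um = NA_real_, flags = "boundary_failure"))
  }
  h <- (interfaces$z3 - interfaces$z2) - ch
  flags <- character()
  if (h < 0) {
    flags <- "negative_clamped"
    h <- 0
  }
  list(asl_um = h, cell_um = ch,
       z2_offset_um = interfaces$z2 - calcein_bounds$z_lower,
       flags = flags)
}

#' ASL height by the fluorescence method
#'
#' Width of the rhodamine-dextran band between its half-maximum boundaries
#' (the conventional dye-based protocol).
#'
#' @param rhodamine_bounds Rhodamine-channel `half_max_bounds`.
#' @return Height in um (`NA` if the bounds are flagged).
#' @export
asl_height_fluorescence <- function(rhodamine_bounds) {
  stopifnot(inherits(rhodamine_bounds, "half_max_bounds"))
  if (!isTRUE(rhodamine_bounds$ok)) return(NA_real_)
  rhodamine_bounds$z_upper - rhodamine_bounds$z_lower
}

#' Measure ASL height at one lateral position
#'
#' Full per-position chain: extract averaged line profiles, locate
#' reflection peaks / fluorescence boundaries, and compute the ASL height by
#' the requested method. Any stage failure yields a flagged row with `NA`
#' height, never a silent `NaN`.
#'
#' @param scan An `asl_scan` (rendered phantom or loaded stack).
#' @param x_index Lateral column (1-based).
#' @param method `"reflection"` (needs reflection + calcein channels) or
#'   `"fluorescence"` (needs rhodamine).
#' @param width Profile averaging width in columns.
#' @param min_prominence,window_halfwidth,r2_threshold Peak-detection and
#'   fit parameters, see [detect_reflection_peaks()].
#' @param well_id,time_min Identifiers carried into the output row.
#' @return One-row tibble: `well_id`, `position`, `time_min`, `method`,
#'   `asl_um`, `cell_um`, `z2_offset_um`, `flags` (`;`-separated, `""` if
#'   clean).
#' @export
measure_position <- function(scan, x_index,
                             method = c("reflection", "fluorescence"),
                             width = 5, min_prominence = 0.1,
                             window_halfwidth = 2, r2_threshold = 0.9,
                             well_id = "well", time_min = 0) {
  method <- match.arg(method)
  stopifnot(inherits(scan, "asl_scan"))
  row <- tibble::tibble(
    well_id = well_id, position = as.integer(x_index),
    time_min = time_min, method = method,
    asl_um = NA_real_, cell_um = NA_real_, z2_offset_um = NA_real_,
    flags = ""
  )

  if (method == "reflection") {
    if (is.null(scan$reflection) || is.null(scan$calcein)) {
      stop("reflection method requires reflection and calcein channels",
           call. = FALSE)
    }
    res <- tryCatch({
      rp <- extract_profile(scan, x_index, width = width,
                            channel = "reflection")
      cp <- extract_profile(scan, x_index, width = width,
                            channel = "calcein")
      peaks <- detect_reflection_peaks(rp, min_prominence = min_prominence,
                                       window_halfwidth = window_halfwidth,
                                       r2_threshold = r2_threshold)
      ifc <- classify_interfaces(peaks)
      bad_fit <- !vapply(ifc$peaks, `[[`, logical(1), "ok")
      cb <- half_max_bounds(cp)
      out <- asl_height_reflection(ifc, cb)
      if (any(bad_fit)) out$flags <- c(out$flags, "low_r_squared")
      out
    },
    asl_insufficient_peaks = function(e) {
      list(asl_um = NA_real_, cell_um = NA_real_, z2_offset_um = NA_real_,
           flags = "insufficient_peaks")
    })
  } else {
    if (is.null(scan$rhodamine)) {
      stop("fluorescence method requires the rhodamine channel",
           call. = FALSE)
    }
    fp <- extract_profile(scan, x_index, width = width,
                          channel = "rhodamine")
    fb <- half_max_bounds(fp)
    h <- asl_height_fluorescence(fb)
    res <- list(asl_um = h, cell_um = NA_real_, z2_offset_um = NA_real_,
                flags = if (is.finite(h)) character() else "boundary_failure")
  }

  row$asl_um <- res$asl_um
  row$cell_um <- res$cell_um
  row$z2_offset_um <- res$z2_offset_um
  row$flags <- paste(res$flags, collapse = ";")
  row
}

#' Measure a scan at all sampling-plan positions
#'
#' Maps a [serpentine_positions()] plan (or explicit column indices) onto
#' lateral columns of the scan and measures each in plan order.
#'
#' @param scan An `asl_scan`.
#' @param positions Integer columns to measure; default places
#'   `n_positions` columns evenly across the central fraction of the field.
#' @param n_positions,central_fraction Used when `positions` is `NULL`.
#' @inheritParams measure_position
#' @param ... Passed to [measure_position()].
#' @return Tibble with one row per position.
#' @export
measure_scan <- function(scan, positions = NULL,
                         method = c("reflection", "fluorescence"),
                         n_positions = 15, central_fraction = 0.6,
                         width = 5, well_id = "well", time_min = NULL, ...) {
  method <- match.arg(method)
  if (is.null(positions)) {
    positions <- central_columns(ncol(scan$reflection), n_positions,
                                 central_fraction, width)
  }
  if (is.null(time_min)) {
    time_min <- if (!is.null(scan$time_min)) scan$time_min else 0
  }
  dplyr::bind_rows(lapply(positions, function(x) {
    measure_position(scan, x, method = method, width = width,
                     well_id = well_id, time_min = time_min, ...)
  }))
}

# Evenly spaced 1-based columns within the central fraction of the field,
# clamped so the averaging window always fits.
central_columns <- function(n_x, n_positions, central_fraction, width = 5) {
  half <- (width - 1) %/% 2
  lo <- max(1 + half, ceiling(n_x * (0.5 - central_fraction / 2)))
  hi <- min(n_x - half, floor(n_x * (0.5 + central_fraction / 2)))
  if (hi < lo) stop("field too narrow for the requested positions",
                    call. = FALSE)
  unique(round(seq(lo, hi, length.out = n_positions)))
}
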