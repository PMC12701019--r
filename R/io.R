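#' Write a scan to a directory of TIFF files
#'
#' One 16-bit grayscale TIFF per channel (`reflection.tif`, `calcein.tif`,
#' `rhodamine.tif`), a `meta.yaml` sidecar with the z spacing and channel
#' list, and — for phantoms — a `truth.csv` ground-truth table (columns
#' `position`, `z1_um`, `z2_um`, `z3_um`, `cell_um`, `asl_um`, one row per
#' lateral column including its tilt offset).
#'
#' @param scan An `asl_scan`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "asl_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  channels <- c("reflection", "calcein", "rhodamine")
  present <- channels[!vapply(scan[channels], is.null, logical(1))]
  for (ch in present) {
    tiff::writeTIFF(scan[[ch]], file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16)
  }
  yaml::write_yaml(
    list(z_spacing_um = scan$z_spacing, channels = as.list(present),
         time_min = if (!is.null(scan$time_min)) scan$time_min else 0),
    file.path(dir, "meta.yaml"))
  if (!is.null(scan$truth)) {
    tr <- scan$truth
    off <- tr$position_offsets
    readr::write_csv(tibble::tibble(
      position = seq_along(off),
      z1_um = tr$z1 + off, z2_um = tr$z2 + off, z3_um = tr$z3 + off,
      cell_um = tr$true_cell_height, asl_um = tr$true_asl_height
    ), file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' Load a scan from a directory of TIFF files
#'
#' Reads the channels named in `channel_map` (defaults to the standard
#' `reflection.tif` / `calcein.tif` / `rhodamine.tif` layout), the
#' `meta.yaml` sidecar, and `truth.csv` when present. A `z_spacing`
#' argument overrides the metadata value (the override wins, with a
#' warning, so a mis-tagged stack can still be processed).
#'
#' @param path Directory written by [write_scan()] (or hand-assembled).
#' @param channel_map Named list/vector mapping channel role to file name.
#' @param z_spacing Optional override of the metadata z spacing (um).
#' @return An `asl_scan`.
#' @export
load_stack <- function(path, channel_map = NULL, z_spacing = NULL) {
  if (!dir.exists(path)) stop("no such scan directory: ", path, call. = FALSE)
  if (is.null(channel_map)) {
    channel_map <- list(reflection = "reflection.tif",
                        calcein = "calcein.tif",
                        rhodamine = "rhodamine.tif")
  }
  meta_path <- file.path(path, "meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  zs <- meta$z_spacing_um
  if (!is.null(z_spacing)) {
    if (!is.null(zs) && !isTRUE(all.equal(z_spacing, zs))) {
      warning(sprintf(
        "z_spacing override %.4g um replaces metadata value %.4g um",
        z_spacing, zs), call. = FALSE)
    }
    zs <- z_spacing
  }
  if (is.null(zs) || zs <= 0) {
    stop("z spacing not in metadata and not supplied", call. = FALSE)
  }
  read_ch <- function(fname) {
    f <- file.path(path, fname)
    if (!file.exists(f)) return(NULL)
    tiff::readTIFF(f)
  }
  scan <- list(
    reflection = read_ch(channel_map$reflection),
    calcein = read_ch(channel_map$calcein),
    rhodamine = read_ch(channel_map$rhodamine),
    z_spacing = zs,
    time_min = if (!is.null(meta$time_min)) meta$time_min else 0,
    truth = NULL
  )
  truth_path <- file.path(path, "truth.csv")
  if (file.exists(truth_path)) {
    tr <- readr::read_csv(truth_path, show_col_types = FALSE)
    mid <- tr[which.min(abs(tr$position - stats::median(tr$position))), ]
    scan$truth <- structure(list(
      z1 = mid$z1_um, z2 = mid$z2_um, z3 = mid$z3_um,
      true_cell_height = mid$cell_um, true_asl_height = mid$asl_um,
      position_offsets = tr$z1_um - mid$z1_um
    ), class = "phantom_truth")
  }
  structure(scan, class = "asl_scan")
}

check_channels <- function(scan, method) {
  if (method %in% c("reflection", "both") &&
      (is.null(scan$reflection) || is.null(scan$calcein))) {
    stop("configuration error: reflection method needs reflection and ",
         "calcein channels", call. = FALSE)
  }
  if (method %in% c("fluorescence", "both") && is.null(scan$rhodamine)) {
    stop("configuration error: fluorescence method needs the rhodamine ",
         "channel", call. = FALSE)
  }
  invisible(scan)
}

#' Run the full measurement pipeline over a directory of wells
#'
#' Each subdirectory of `input_dir` is one well (a scan written by
#' [write_scan()] or an equivalent TIFF layout). Every well is measured at
#' the sampling-plan positions, summarized, and — when `groups` assigns
#' wells to exactly two groups — compared. Outputs are tidy CSVs plus a
#' JSON run manifest carrying the seed and a config hash; reruns with the
#' same seed are byte-identical.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `input_dir`; `output_dir`; `method` (`"reflection"`, `"fluorescence"`
#'   or `"both"`); optional `n_positions`, `central_fraction`, `width`,
#'   `z_spacing` (override), `groups` (named list well_id -> group label),
#'   `test` (default `"unpaired_t"`), `alpha` (default 0.05), `seed`.
#' @return List with `positions`, `summaries`, `comparisons` tibbles and
#'   the manifest, invisibly; CSVs are written to `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    method = "reflection", n_positions = 15, central_fraction = 0.6,
    width = 5, z_spacing = NULL, groups = NULL, test = "unpaired_t",
    alpha = 0.05, seed = 0
  ), config)
  if (is.null(cfg$input_dir) || is.null(cfg$output_dir)) {
    stop("config must give input_dir and output_dir", call. = FALSE)
  }
  wells <- sort(list.dirs(cfg$input_dir, recursive = FALSE))
  if (length(wells) == 0) {
    stop("no well subdirectories found in ", cfg$input_dir, call. = FALSE)
  }
  methods <- if (cfg$method == "both") c("reflection", "fluorescence")
             else cfg$method

  positions <- dplyr::bind_rows(lapply(wells, function(w) {
    scan <- load_stack(w, z_spacing = cfg$z_spacing)
    check_channels(scan, cfg$method)
    dplyr::bind_rows(lapply(methods, function(m) {
      measure_scan(scan, method = m, n_positions = cfg$n_positions,
                   central_fraction = cfg$central_fraction,
                   width = cfg$width, well_id = basename(w))
    }))
  }))

  grp <- dplyr::group_by(positions, .data$well_id, .data$time_min,
                         .data$method)
  keys <- dplyr::group_keys(grp)
  splits <- dplyr::group_split(grp)
  summaries <- dplyr::bind_rows(lapply(seq_along(splits), function(i) {
    s <- tryCatch(summarize_well(splits[[i]]), error = function(e) NULL)
    if (is.null(s)) {
      stop(sprintf(
        "well '%s' (t=%s, %s) has no usable positions; flags: %s",
        keys$well_id[i], keys$time_min[i], keys$method[i],
        paste(unique(splits[[i]]$flags), collapse = " ")), call. = FALSE)
    }
    s
  }))

  comparisons <- NULL
  if (!is.null(cfg$groups)) {
    labels <- unlist(cfg$groups)
    summaries$group <- labels[summaries$well_id]
    lv <- sort(unique(stats::na.omit(summaries$group)))
    if (length(lv) == 2) {
      comparisons <- dplyr::bind_rows(lapply(methods, function(m) {
        sm <- summaries[summaries$method == m & !is.na(summaries$group), ]
        cmp <- compare_groups(sm$mean_um[sm$group == lv[1]],
                              sm$mean_um[sm$group == lv[2]],
                              test = cfg$test)
        cmp$method <- m
        cmp$group_a <- lv[1]; cmp$group_b <- lv[2]
        cmp
      }))
      comparisons$adjusted_p <- bky_adjust(comparisons$p_value,
                                           alpha = cfg$alpha)
    }
  }

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(positions, file.path(cfg$output_dir, "positions.csv"))
  readr::write_csv(summaries, file.path(cfg$output_dir, "summaries.csv"))
  if (!is.null(comparisons)) {
    readr::write_csv(comparisons, file.path(cfg$output_dir,
                                            "comparisons.csv"))
  }
  manifest <- list(
    seed = cfg$seed,
    n_wells = length(wells),
    wells = basename(wells),
    method = cfg$method,
    config_hash = rlang::hash(cfg)
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(positions = positions, summaries = summaries,
                 comparisons = comparisons, manifest = manifest))
}
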