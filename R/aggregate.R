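#' Serpentine sampling plan
#'
#' Pre-defined measurement positions on a rows x cols grid confined to the
#' central area of the culture (avoiding meniscus effects), traversed in
#' serpentine order: row 1 left to right, row 2 right to left, and so on.
#'
#' @param rows,cols Grid size (default 3 x 5 = 15 positions).
#' @param central_fraction Fraction of the field, centred, that the grid
#'   spans in each axis (default 0.6).
#' @return A `sampling_plan` tibble: `order`, `row`, `col`, and fractional
#'   field coordinates `u`, `v` in `[0, 1]`.
#' @export
serpentine_positions <- function(rows = 3, cols = 5, central_fraction = 0.6) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1", call. = FALSE)
  if (central_fraction <= 0 || central_fraction > 1) {
    stop("central_fraction must be in (0, 1]", call. = FALSE)
  }
  grid_axis <- function(n) {
    if (n == 1) 0.5 else 0.5 + central_fraction * ((seq_len(n) - 1) / (n - 1) - 0.5)
  }
  us <- grid_axis(cols)
  vs <- grid_axis(rows)
  out <- vector("list", rows)
  for (r in seq_len(rows)) {
    cols_order <- if (r %% 2 == 1) seq_len(cols) else rev(seq_len(cols))
    out[[r]] <- tibble::tibble(row = r, col = cols_order,
                               u = us[cols_order], v = vs[r])
  }
  plan <- dplyr::bind_rows(out)
  plan$order <- seq_len(nrow(plan))
  structure(plan[, c("order", "row", "col", "u", "v")],
            class = c("sampling_plan", class(plan)))
}

usable_measurements <- function(measurements) {
  # exclude hard failures; keep clamped-to-zero positions (design: clamping,
  # not dropping, avoids upward bias of the well mean)
  bad <- c("insufficient_peaks", "boundary_failure", "fit_failed",
           "low_r_squared")
  flagged <- vapply(strsplit(measurements$flags, ";", fixed = TRUE),
                    function(f) any(f %in% bad), logical(1))
  measurements[!flagged & is.finite(measurements$asl_um), , drop = FALSE]
}

#' Summarize one well at one time point
#'
#' Mean, SD, SEM and coefficient of variation (CV = 100 SD / mean) of the
#' usable per-position ASL heights. Positions carrying failure flags are
#' excluded and counted; clamped-to-zero positions are kept.
#'
#' @param measurements Tibble of per-position rows from [measure_scan()],
#'   all from one well / time point / method.
#' @return One-row tibble: `well_id`, `time_min`, `method`, `n_positions`,
#'   `n_flagged`, `mean_um`, `sd_um`, `sem_um`, `cv_pct`.
#' @export
summarize_well <- function(measurements) {
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1)
  key <- unique(measurements[, c("well_id", "time_min", "method")])
  if (nrow(key) != 1) {
    stop("summarize_well expects a single well/time/method group; ",
         "group and map for multi-well input", call. = FALSE)
  }
  use <- usable_measurements(measurements)
  n <- nrow(use)
  if (n < 2) {
    stop(sprintf("insufficient usable positions (%d of %d) in well '%s'",
                 n, nrow(measurements), key$well_id), call. = FALSE)
  }
  m <- mean(use$asl_um)
  s <- stats::sd(use$asl_um)
  tibble::tibble(
    well_id = key$well_id, time_min = key$time_min, method = key$method,
    n_positions = n, n_flagged = nrow(measurements) - n,
    mean_um = m, sd_um = s, sem_um = s / sqrt(n),
    cv_pct = if (m > 0) 100 * s / m else NA_real_
  )
}

#' Subsampling stability of the well summary
#'
#' How stable are mean, SD and CV as the number of sampled positions
#' varies? For each size, draws `n_reps` random subsets without replacement
#' and reports the averages of the subset summaries. Used to justify a
#' 15-position plan.
#'
#' @param measurements Per-position tibble (one well/time/method).
#' @param sizes Subset sizes, each <= number of usable positions.
#' @param n_reps Replicates per size (default 200).
#' @param seed Seed for reproducible draws.
#' @return Tibble: `size`, `n_reps`, `mean_of_means_um`, `mean_sd_um`,
#'   `mean_cv_pct`.
#' @export
subsample_stability <- function(measurements, sizes = c(10, 15, 20),
                                n_reps = 200, seed = NULL) {
  use <- usable_measurements(measurements)
  n <- nrow(use)
  if (any(sizes > n)) {
    stop(sprintf("subset size exceeds available positions (%d)", n),
         call. = FALSE)
  }
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  with_seed(seed, {
    dplyr::bind_rows(lapply(sizes, function(k) {
      reps <- vapply(seq_len(n_reps), function(r) {
        sub <- use[sample.int(n, k), , drop = FALSE]
        m <- mean(sub$asl_um); s <- stats::sd(sub$asl_um)
        c(m, s, if (m > 0) 100 * s / m else NA_real_)
      }, numeric(3))
      tibble::tibble(size = k, n_reps = n_reps,
                     mean_of_means_um = mean(reps[1, ]),
                     mean_sd_um = mean(reps[2, ]),
                     mean_cv_pct = mean(reps[3, ]))
    }))
  })
}

#' Time-course table of well summaries
#'
#' Orders well summaries by time for plotting mean +/- SEM traces and for
#' extracting checkpoints (e.g. 0 / 2 / 6 / 24 h after a volume challenge).
#'
#' @param summaries Tibble of [summarize_well()] rows.
#' @return The same tibble sorted by `well_id`, `method`, `time_min`.
#' @export
timecourse <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  dup <- duplicated(summaries[, c("well_id", "method", "time_min")])
  if (any(dup)) {
    stop("duplicate time points for a well/method: ",
         paste(unique(summaries$time_min[dup]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(summaries, .data$well_id, .data$method, .data$time_min)
}
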