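#' Conventional FVE neglect indicators for a single trial
#'
#' The four established indicators of visuospatial bias during free visual
#' exploration, computed on the fixations of one participant x picture trial:
#' mean horizontal gaze position (the centre of mass of the fixation
#' distribution, in degrees from the picture centre; negative = left),
#' the horizontal position of the leftmost fixation, the number of
#' fixations per screen half, and the cumulative fixation duration per half.
#'
#' `mean_gaze_position()` is the unweighted mean over fixations; pass
#' `weight_by_duration = TRUE` for a duration-weighted variant.
#'
#' @param fixations Tibble of fixation records for one trial (needs `x_px`;
#'   `cumulative_duration_per_region()` also needs `duration_ms`).
#' @param geometry A [screen_geometry()] object.
#' @param weight_by_duration Weight the mean by fixation duration.
#' @return `mean_gaze_position()` and `leftmost_fixation()` return degrees
#'   (`NA` for an empty trial); `fixation_count_per_region()` and
#'   `cumulative_duration_per_region()` return named numeric vectors with
#'   elements `left` and `right`.
#' @export
mean_gaze_position <- function(fixations, geometry,
                               weight_by_duration = FALSE) {
  if (nrow(fixations) == 0) return(NA_real_)
  deg <- deg_from_center(fixations$x_px, geometry)
  if (weight_by_duration) {
    stats::weighted.mean(deg, fixations$duration_ms)
  } else {
    mean(deg)
  }
}

#' @rdname mean_gaze_position
#' @export
leftmost_fixation <- function(fixations, geometry) {
  if (nrow(fixations) == 0) return(NA_real_)
  min(deg_from_center(fixations$x_px, geometry))
}

#' @rdname mean_gaze_position
#' @export
fixation_count_per_region <- function(fixations, geometry) {
  region <- assign_region(fixations$x_px, geometry)
  c(left = sum(region == "left"), right = sum(region == "right"))
}

#' @rdname mean_gaze_position
#' @export
cumulative_duration_per_region <- function(fixations, geometry) {
  region <- assign_region(fixations$x_px, geometry)
  c(left = sum(fixations$duration_ms[region == "left"]),
    right = sum(fixations$duration_ms[region == "right"]))
}

#' Horizontal fixation histogram
#'
#' Counts fixations in horizontal bins of `bin_width_deg` degrees of visual
#' angle spanning the screen width `[-h_deg/2, +h_deg/2]`. Bins are
#' half-open `[lo, hi)` with the last bin closed; when the width does not
#' divide evenly, the final bin is truncated at `+h_deg/2`. Positions
#' outside the range (off-screen fixations) are clamped into the boundary
#' bins so the counts always sum to the number of fixations.
#'
#' @param fixations Tibble of fixation records (e.g., all fixations of a
#'   group, for a cumulative spatial-distribution plot).
#' @param geometry A [screen_geometry()] object.
#' @param bin_width_deg Bin width in degrees (default 2).
#' @return Tibble with columns `bin_lo`, `bin_hi` (degrees) and `count`.
#' @export
horizontal_histogram <- function(fixations, geometry, bin_width_deg = 2) {
  if (bin_width_deg <= 0) stop("bin_width_deg must be positive", call. = FALSE)
  half <- geometry$h_deg / 2
  breaks <- seq(-half, half, by = bin_width_deg)
  if (max(breaks) < half) breaks <- c(breaks, half)
  deg <- deg_from_center(fixations$x_px, geometry)
  deg <- pmin(pmax(deg, -half), half)
  # findInterval with left-closed bins; values equal to the last break fall
  # into the final bin
  idx <- findInterval(deg, breaks, rightmost.closed = TRUE, left.open = FALSE)
  idx <- pmin(pmax(idx, 1L), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    count = counts
  )
}

#' Conventional metrics table for a whole dataset
#'
#' Computes the four conventional indicators for every participant x picture
#' trial and their per-participant averages over pictures (rows with
#' `picture_id = "ALL"`). Variables are first computed per picture and then
#' averaged over pictures within participant, following standard FVE
#' practice. Zero-fixation metrics that are undefined (gaze position,
#' leftmost) are missing and excluded from averages; counts and durations
#' are genuinely 0 for pictures a participant produced no fixations on
#' in that region.
#'
#' @param dataset An [fve_dataset()] (typically duration-filtered).
#' @param weight_by_duration Passed to [mean_gaze_position()].
#' @return Long-format metrics tibble (see [write_metrics()]) with metrics
#'   `mean_gaze_deg` and `leftmost_deg` (region `"total"`), and `n_fix` and
#'   `cum_dur_ms` (regions `"left"`, `"right"`).
#' @export
conventional_metrics <- function(dataset, weight_by_duration = FALSE) {
  stopifnot(inherits(dataset, "fve_dataset"))
  geom <- dataset$geometry
  fix <- dataset$fixations
  if (nrow(fix) == 0) return(empty_metrics())
  per_trial <- dplyr::group_modify(
    dplyr::group_by(fix, .data$participant_id, .data$group, .data$picture_id),
    function(d, key) {
      counts <- fixation_count_per_region(d, geom)
      durs <- cumulative_duration_per_region(d, geom)
      tibble::tibble(
        region = c("total", "total", "left", "right", "left", "right"),
        metric = c("mean_gaze_deg", "leftmost_deg",
                   "n_fix", "n_fix", "cum_dur_ms", "cum_dur_ms"),
        value = c(mean_gaze_position(d, geom, weight_by_duration),
                  leftmost_fixation(d, geom),
                  counts[["left"]], counts[["right"]],
                  durs[["left"]], durs[["right"]])
      )
    }
  )
  per_trial <- dplyr::ungroup(per_trial)
  averaged <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$participant_id, .data$group,
                    .data$region, .data$metric),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  averaged$picture_id <- "ALL"
  out <- dplyr::bind_rows(per_trial, averaged)
  out[c("participant_id", "group", "picture_id", "region", "metric", "value")]
}
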