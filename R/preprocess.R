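#' Filter fixations by duration
#'
#' Retains fixations whose duration lies within `[min_ms, max_ms]`
#' (inclusive on both ends), the standard event filter for FVE recordings.
#' `order_index` is reassigned contiguously within each
#' participant x picture trial after filtering.
#'
#' The exclusion fraction is reported so users can compare their own data
#' against typical values; it is not asserted against any reference.
#'
#' @param dataset An [fve_dataset()].
#' @param min_ms,max_ms Inclusive duration bounds in milliseconds.
#' @return A list with elements `dataset` (filtered `fve_dataset`),
#'   `excluded_fraction` (pooled proportion of fixations removed; 0 for an
#'   empty dataset) and `excluded_by_participant` (tibble with per-participant
#'   fractions).
#' @export
filter_by_duration <- function(dataset, min_ms = 100, max_ms = 2000) {
  stopifnot(inherits(dataset, "fve_dataset"))
  if (min_ms >= max_ms) stop("min_ms must be < max_ms", call. = FALSE)
  fix <- dataset$fixations
  if (nrow(fix) == 0) {
    return(list(dataset = dataset, excluded_fraction = 0,
                excluded_by_participant = tibble::tibble(
                  participant_id = character(), excluded_fraction = numeric())))
  }
  keep <- fix$duration_ms >= min_ms & fix$duration_ms <= max_ms
  per_part <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(participant_id = fix$participant_id,
                                   excluded = !keep),
                    .data$participant_id),
    excluded_fraction = mean(.data$excluded), .groups = "drop"
  )
  out <- fve_dataset(fix[keep, ], dataset$geometry,
                     dataset$pictures_per_participant)
  list(
    dataset = out,
    excluded_fraction = mean(!keep),
    excluded_by_participant = per_part
  )
}

#' Assign each fixation to a screen half
#'
#' The left half comprises pixel columns `0 .. width_px/2 - 1`, the right
#' half the remainder; a fixation centre exactly on the split column belongs
#' to the right half.
#'
#' @param x_px Horizontal pixel coordinate(s), 0-based.
#' @param geometry A [screen_geometry()] object.
#' @return Character vector, `"left"` or `"right"`.
#' @examples
#' assign_region(c(599, 600), screen_geometry())
#' @export
assign_region <- function(x_px, geometry) {
  stopifnot(inherits(geometry, "fve_geometry"))
  ifelse(x_px < geometry$width_px / 2, "left", "right")
}
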