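#' Construct an FVE dataset
#'
#' Bundles a tibble of fixation records with the screen geometry they were
#' recorded on. Records are sorted by participant, picture and onset, and
#' `order_index` (the temporal rank of a fixation within its
#' participant x picture trial) is derived from the onsets.
#'
#' @param fixations A data frame with columns `participant_id`, `group`
#'   (`"control"` or `"patient"`), `picture_id`, `onset_ms`, `duration_ms`,
#'   `x_px`, `y_px`. An `order_index` column, if present, is recomputed.
#' @param geometry A [screen_geometry()] object.
#' @param pictures_per_participant Nominal number of pictures shown to each
#'   participant (informational; default 24).
#' @return An object of class `fve_dataset`: a list with elements
#'   `fixations` (tibble), `geometry` and `pictures_per_participant`.
#' @export
fve_dataset <- function(fixations, geometry = screen_geometry(),
                        pictures_per_participant = 24) {
  stopifnot(inherits(geometry, "fve_geometry"))
  req <- c("participant_id", "group", "picture_id", "onset_ms",
           "duration_ms", "x_px", "y_px")
  missing_cols <- setdiff(req, names(fixations))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fix <- tibble::as_tibble(fixations)
  fix$participant_id <- as.character(fix$participant_id)
  fix$group <- as.character(fix$group)
  fix$picture_id <- as.character(fix$picture_id)
  bad_group <- setdiff(unique(fix$group), c("control", "patient"))
  if (length(bad_group)) {
    stop("group must be 'control' or 'patient'; found: ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  }
  if (any(fix$duration_ms <= 0, na.rm = TRUE)) {
    stop("duration_ms must be positive", call. = FALSE)
  }
  fix <- dplyr::arrange(fix, .data$participant_id, .data$picture_id,
                        .data$onset_ms)
  fix <- dplyr::mutate(
    dplyr::group_by(fix, .data$participant_id, .data$picture_id),
    order_index = dplyr::row_number()
  )
  fix <- dplyr::ungroup(fix)
  structure(
    list(fixations = fix, geometry = geometry,
         pictures_per_participant = as.integer(pictures_per_participant)),
    class = "fve_dataset"
  )
}

#' @export
print.fve_dataset <- function(x, ...) {
  n_part <- length(unique(x$fixations$participant_id))
  cat(sprintf("<fve_dataset> %d fixations, %d participant(s), %d picture id(s)\n",
              nrow(x$fixations), n_part,
              length(unique(x$fixations$picture_id))))
  print(x$geometry)
  invisible(x)
}

#' Read fixation records from CSV
#'
#' Reads a comma-separated, UTF-8, "."-decimal fixation file with a header
#' row and columns `participant_id`, `group`, `picture_id`, `onset_ms`,
#' `duration_ms`, `x_px`, `y_px` (`order_index` is derived, not read).
#' Rows with non-numeric or missing numeric fields are dropped with a
#' warning reporting their (1-based, data-row) numbers. Records arriving out
#' of onset order are re-sorted with a warning.
#'
#' Fixations with coordinates outside the picture bounds are retained but
#' flagged in the logical column `off_screen`; downstream raster code clips
#' their foveal disks at the picture edge.
#'
#' @param path Path to the CSV file.
#' @param geometry A [screen_geometry()] object.
#' @param pictures_per_participant Passed to [fve_dataset()].
#' @return An `fve_dataset`.
#' @export
read_fixations <- function(path, geometry = screen_geometry(),
                           pictures_per_participant = 24) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("participant_id", "group", "picture_id", "onset_ms",
           "duration_ms", "x_px", "y_px")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("no data rows in ", path, call. = FALSE)
    empty <- tibble::tibble(
      participant_id = character(), group = character(),
      picture_id = character(), onset_ms = numeric(),
      duration_ms = numeric(), x_px = numeric(), y_px = numeric()
    )
    return(fve_dataset(empty, geometry, pictures_per_participant))
  }
  num_cols <- c("onset_ms", "duration_ms", "x_px", "y_px")
  parsed <- raw
  for (cc in num_cols) {
    suppressWarnings(parsed[[cc]] <- as.numeric(raw[[cc]]))
  }
  bad <- which(Reduce(`|`, lapply(parsed[num_cols], is.na)))
  if (length(bad)) {
    warning("dropping ", length(bad), " malformed row(s): ",
            paste(utils::head(bad, 20), collapse = ", "),
            if (length(bad) > 20) ", ..." else "", call. = FALSE)
    parsed <- parsed[-bad, ]
  }
  unsorted <- any(unlist(tapply(
    parsed$onset_ms,
    interaction(parsed$participant_id, parsed$picture_id, drop = TRUE),
    function(v) is.unsorted(v, strictly = FALSE)
  )))
  if (isTRUE(unsorted)) {
    warning("fixation onsets were out of order; records re-sorted and ",
            "order_index reassigned", call. = FALSE)
  }
  parsed$off_screen <- parsed$x_px < 0 | parsed$x_px > geometry$width_px - 1 |
    parsed$y_px < 0 | parsed$y_px > geometry$height_px - 1
  fve_dataset(parsed, geometry, pictures_per_participant)
}

#' Write and read a long-format metrics table
#'
#' Metrics tables are long-format tibbles with columns `participant_id`,
#' `group`, `picture_id` (or `"ALL"` for per-participant averages), `region`
#' (`"left"`, `"right"` or `"total"`), `metric` and `value`. The CSV
#' round-trip is lossless to full double precision.
#'
#' @param table A metrics tibble as described above.
#' @param path Output/input CSV path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns the tibble.
#' @export
write_metrics <- function(table, path) {
  req <- c("participant_id", "group", "picture_id", "region", "metric", "value")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("metrics table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(table[req], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      picture_id = readr::col_character(),
      region = readr::col_character(),
      metric = readr::col_character(),
      value = readr::col_double()
    ),
    progress = FALSE
  )
}

# Schema for an empty long-format metrics table.
empty_metrics <- function() {
  tibble::tibble(participant_id = character(), group = character(),
                 picture_id = character(), region = character(),
                 metric = character(), value = numeric())
}
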