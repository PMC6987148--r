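# Pairwise fixation distances in degrees of visual angle. Pixel offsets are
# converted per axis (anisotropic pixels), since all thresholds are angular.
fixation_deg_coords <- function(fixations, geometry) {
  cbind(
    x = fixations$x_px / px_per_degree(geometry, "horizontal"),
    y = fixations$y_px / px_per_degree(geometry, "vertical")
  )
}

#' Classify fixations as single vs. overlapping
#'
#' A fixation is *single* when no other fixation of the same trial — in any
#' temporal order — lies within twice the foveal radius of its centre
#' (strictly closer than `2 * radius_deg`), i.e., its foveal disk intersects
#' no other disk with positive area. All remaining fixations are
#' *overlapping*. Distances are measured in degrees using per-axis pixel
#' scaling.
#'
#' @param fixations Tibble of fixation records for one trial.
#' @param geometry A [screen_geometry()] object.
#' @param radius_deg Foveal radius in degrees (default 1).
#' @return The input tibble with an added character column `overlap_status`
#'   (`"single"` or `"overlapping"`).
#' @export
classify_overlap <- function(fixations, geometry, radius_deg = 1) {
  n <- nrow(fixations)
  out <- tibble::as_tibble(fixations)
  if (n == 0) {
    out$overlap_status <- character(0)
    return(out)
  }
  if (n == 1) {
    out$overlap_status <- "single"
    return(out)
  }
  xy <- fixation_deg_coords(fixations, geometry)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  near <- unname(apply(d, 1, min)) < 2 * radius_deg
  out$overlap_status <- ifelse(near, "overlapping", "single")
  out
}

#' Split overlapping fixations into capture, re-capture and other
#'
#' Processes fixations in temporal order. An overlapping fixation is a
#' *capture* when it lands strictly within `threshold_deg` of its
#' immediately preceding fixation (successive refixation, the signature of
#' impaired attentional disengagement); failing that, it is a *re-capture*
#' when it lands within `threshold_deg` of some temporally distant
#' (non-adjacent) earlier fixation (a spatial-working-memory revisit).
#' Capture takes precedence when both hold. Overlapping fixations within
#' `2 * radius` of a neighbour but not within `threshold_deg` of any
#' *prior* fixation (e.g., their only near neighbour comes later) are
#' labelled `"other"` rather than silently merged. Single fixations get
#' `"not-applicable"`.
#'
#' With `threshold_deg = 2 * radius_deg` the two criteria coincide and
#' `"other"` is possible only for overlaps whose near neighbours all lie in
#' the future.
#'
#' @param fixations Output of [classify_overlap()] (must carry
#'   `overlap_status` and be orderable by `order_index` or row order).
#' @param geometry A [screen_geometry()] object.
#' @param threshold_deg Revisit distance threshold in degrees (default 1).
#' @return The tibble with an added character column `subtype`
#'   (`"capture"`, `"re-capture"`, `"other"`, `"not-applicable"`), in
#'   temporal order.
#' @export
classify_capture_recapture <- function(fixations, geometry,
                                       threshold_deg = 1) {
  if (!"overlap_status" %in% names(fixations)) {
    stop("run classify_overlap() first", call. = FALSE)
  }
  out <- tibble::as_tibble(fixations)
  n <- nrow(out)
  if (n == 0) {
    out$subtype <- character(0)
    return(out)
  }
  if ("order_index" %in% names(out)) {
    out <- out[order(out$order_index), ]
  }
  xy <- fixation_deg_coords(out, geometry)
  subtype <- rep("not-applicable", n)
  for (i in seq_len(n)) {
    if (out$overlap_status[i] != "overlapping") next
    if (i == 1) {
      subtype[i] <- "other"
      next
    }
    dprev <- sqrt(sum((xy[i, ] - xy[i - 1, ])^2))
    if (dprev < threshold_deg) {
      subtype[i] <- "capture"
    } else if (i > 2) {
      dpast <- sqrt(rowSums((xy[seq_len(i - 2), , drop = FALSE] -
                               matrix(xy[i, ], i - 2, 2, byrow = TRUE))^2))
      subtype[i] <- if (any(dpast < threshold_deg)) "re-capture" else "other"
    } else {
      subtype[i] <- "other"
    }
  }
  out$subtype <- subtype
  out
}

#' Classify every trial of a dataset
#'
#' Applies [classify_overlap()] and [classify_capture_recapture()] to each
#' participant x picture trial.
#'
#' @param dataset An [fve_dataset()] (typically duration-filtered).
#' @param radius_deg Foveal radius in degrees.
#' @param threshold_deg Capture/re-capture threshold in degrees.
#' @param consistent_thresholds If `TRUE`, force
#'   `threshold_deg = 2 * radius_deg` so every overlapping fixation with a
#'   prior near neighbour is forced into capture/re-capture.
#' @return The `fve_dataset` with `overlap_status` and `subtype` columns
#'   added to its fixation tibble.
#' @export
classify_dataset <- function(dataset, radius_deg = 1, threshold_deg = 1,
                             consistent_thresholds = FALSE) {
  stopifnot(inherits(dataset, "fve_dataset"))
  if (consistent_thresholds) threshold_deg <- 2 * radius_deg
  geom <- dataset$geometry
  if (nrow(dataset$fixations) == 0) {
    fix <- dataset$fixations
    fix$overlap_status <- character(0)
    fix$subtype <- character(0)
    return(fve_dataset(fix, geom, dataset$pictures_per_participant))
  }
  fix <- dplyr::group_modify(
    dplyr::group_by(dataset$fixations, .data$participant_id, .data$picture_id),
    function(d, key) {
      classify_capture_recapture(
        classify_overlap(d, geom, radius_deg), geom, threshold_deg)
    }
  )
  fix <- dplyr::ungroup(fix)
  fve_dataset(fix, geom, dataset$pictures_per_participant)
}

#' Per-region classification counts for one classified trial
#'
#' Tallies fixation classes by the screen half of each fixation's own
#' centre. The partition identities
#' `n_single + n_overlap = n_fix` and
#' `n_capture + n_recapture + n_other = n_overlap` hold per region by
#' construction.
#'
#' @param classified Output of [classify_capture_recapture()].
#' @param geometry A [screen_geometry()] object.
#' @return Tibble with one row per region (`left`, `right`, `total`) and
#'   columns `n_fix`, `n_single`, `n_overlap`, `n_capture`, `n_recapture`,
#'   `n_other`.
#' @export
class_counts <- function(classified, geometry) {
  region <- if (nrow(classified)) {
    assign_region(classified$x_px, geometry)
  } else {
    character(0)
  }
  tally <- function(keep) {
    st <- classified$overlap_status[keep]
    sub <- classified$subtype[keep]
    tibble::tibble(
      n_fix = sum(keep), n_single = sum(st == "single"),
      n_overlap = sum(st == "overlapping"),
      n_capture = sum(sub == "capture"),
      n_recapture = sum(sub == "re-capture"),
      n_other = sum(sub == "other")
    )
  }
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(region = "left"), tally(region == "left")),
    dplyr::bind_cols(tibble::tibble(region = "right"), tally(region == "right")),
    dplyr::bind_cols(tibble::tibble(region = "total"),
                     tally(rep(TRUE, nrow(classified))))
  )
}

#' Proportion of overlapping fixations
#'
#' The ratio of overlapping to single fixations, the clustering index used
#' to compare screen halves and groups. Undefined (missing) when there are
#' no single fixations.
#'
#' @param counts A row (or tibble) from [class_counts()], or anything with
#'   `n_overlap` and `n_single` columns.
#' @param region Optional region to select when `counts` has a `region`
#'   column.
#' @return Numeric ratio, `NA` where `n_single` is 0.
#' @export
overlap_proportion <- function(counts, region = NULL) {
  if (!is.null(region) && "region" %in% names(counts)) {
    counts <- counts[counts$region == region, ]
  }
  ifelse(counts$n_single > 0, counts$n_overlap / counts$n_single, NA_real_)
}

#' Classification metrics table for a whole dataset
#'
#' Per participant x picture x region counts of every fixation class, plus
#' the overlap proportion, and their per-participant averages over pictures
#' (`picture_id = "ALL"`). The overlap proportion is computed per picture
#' and averaged over the pictures where it is defined (at least one single
#' fixation in the region).
#'
#' @param dataset A classified [fve_dataset()] (see [classify_dataset()]).
#' @return Long-format metrics tibble with metrics `n_single`, `n_overlap`,
#'   `n_capture`, `n_recapture`, `n_other`, `prop_overlap`.
#' @export
class_metrics <- function(dataset) {
  stopifnot(inherits(dataset, "fve_dataset"))
  if (!"subtype" %in% names(dataset$fixations)) {
    stop("dataset is not classified; run classify_dataset() first",
         call. = FALSE)
  }
  geom <- dataset$geometry
  if (nrow(dataset$fixations) == 0) return(empty_metrics())
  per_trial <- dplyr::group_modify(
    dplyr::group_by(dataset$fixations, .data$participant_id, .data$group,
                    .data$picture_id),
    function(d, key) {
      cc <- class_counts(d, geom)
      cc$prop_overlap <- overlap_proportion(cc)
      tidyr::pivot_longer(cc, -"region", names_to = "metric",
                          values_to = "value")
    }
  )
  per_trial <- dplyr::ungroup(per_trial)
  per_trial <- per_trial[per_trial$metric != "n_fix", ]
  averaged <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$participant_id, .data$group,
                    .data$region, .data$metric),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  averaged$picture_id <- "ALL"
  averaged$value[is.nan(averaged$value)] <- NA_real_
  out <- dplyr::bind_rows(per_trial, averaged)
  out[c("participant_id", "group", "picture_id", "region", "metric", "value")]
}

#' Temporal dynamics of capture and re-capture fixations
#'
#' For each trial and each prefix length `k = 1..k_max`, the percentage of
#' the first `k` fixations that are capture (resp. re-capture) fixations.
#' Pictures contribute at every `k` up to their own fixation count.
#' Percentages are averaged over pictures within participant, then over
#' participants within group; the standard error is across participants.
#'
#' @param dataset A classified [fve_dataset()].
#' @param k_max Longest prefix considered (default 20).
#' @return Tibble with columns `group`, `subtype` (`"capture"`,
#'   `"re-capture"`), `k`, `mean_pct`, `sem`.
#' @export
temporal_dynamics <- function(dataset, k_max = 20) {
  stopifnot(inherits(dataset, "fve_dataset"))
  if (!"subtype" %in% names(dataset$fixations)) {
    stop("dataset is not classified; run classify_dataset() first",
         call. = FALSE)
  }
  if (nrow(dataset$fixations) == 0) {
    return(tibble::tibble(group = character(), subtype = character(),
                          k = integer(), mean_pct = numeric(),
                          sem = numeric()))
  }
  prefix_pct <- function(labels, what) {
    n <- min(length(labels), k_max)
    if (n == 0) return(NULL)
    k <- seq_len(n)
    tibble::tibble(subtype = what, k = k,
                   pct = 100 * cumsum(labels[k] == what) / k)
  }
  per_trial <- dplyr::group_modify(
    dplyr::group_by(dataset$fixations, .data$participant_id, .data$group,
                    .data$picture_id),
    function(d, key) {
      labels <- d$subtype[order(d$order_index)]
      dplyr::bind_rows(prefix_pct(labels, "capture"),
                       prefix_pct(labels, "re-capture"))
    }
  )
  per_trial <- dplyr::ungroup(per_trial)
  per_part <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$participant_id, .data$group,
                    .data$subtype, .data$k),
    pct = mean(.data$pct), .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(per_part, .data$group, .data$subtype, .data$k),
    mean_pct = mean(.data$pct),
    sem = stats::sd(.data$pct) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}
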