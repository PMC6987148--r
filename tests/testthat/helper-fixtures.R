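# Shared fixtures and independent oracles. The oracles deliberately use the
# plainest possible formulation (per-cell scans, double loops) so they stay
# independent of the optimized implementation paths they check.

make_fix <- function(x, y = rep(450, length(x)),
                     dur = rep(200, length(x)),
                     participant = "p1", group = "control",
                     picture = "pic1") {
  n <- length(x)
  tibble::tibble(
    participant_id = participant, group = group, picture_id = picture,
    onset_ms = seq(0, by = 250, length.out = n),
    duration_ms = dur, x_px = x, y_px = y,
    order_index = seq_len(n)
  )
}

make_dataset <- function(fix, geometry = screen_geometry(), ...) {
  fve_dataset(fix, geometry, ...)
}

# Naive per-pixel distance scan: every cell (row, col), at 0-based coords
# (x = col, y = row), is tested against every fixation centre over the full
# grid — no bounding boxes or other shortcuts.
naive_raster <- function(fixations, geometry) {
  w <- geometry$width_px
  h <- geometry$height_px
  r <- foveal_radius_px(geometry)
  cells <- expand.grid(row = 0:(h - 1), col = 0:(w - 1))
  if (nrow(fixations) == 0) {
    return(matrix(FALSE, nrow = h, ncol = w))
  }
  d2 <- outer(cells$col, fixations$x_px, `-`)^2 +
    outer(cells$row, fixations$y_px, `-`)^2
  covered <- rowSums(d2 <= r^2) > 0
  matrix(covered, nrow = h, ncol = w)
}

# Brute-force reimplementation of the fixation taxonomy rules, written
# directly from their definitions with explicit double loops.
naive_classify <- function(fixations, geometry, radius_deg = 1,
                           threshold_deg = 1) {
  n <- nrow(fixations)
  ppd_h <- geometry$width_px / geometry$h_deg
  ppd_v <- geometry$height_px / geometry$v_deg
  ddeg <- function(i, j) {
    sqrt(((fixations$x_px[i] - fixations$x_px[j]) / ppd_h)^2 +
           ((fixations$y_px[i] - fixations$y_px[j]) / ppd_v)^2)
  }
  status <- character(n)
  for (i in seq_len(n)) {
    single <- TRUE
    for (j in seq_len(n)) {
      if (j != i && ddeg(i, j) < 2 * radius_deg) single <- FALSE
    }
    status[i] <- if (single) "single" else "overlapping"
  }
  subtype <- rep("not-applicable", n)
  for (i in seq_len(n)) {
    if (status[i] != "overlapping") next
    if (i > 1 && ddeg(i, i - 1) < threshold_deg) {
      subtype[i] <- "capture"
      next
    }
    found <- FALSE
    if (i > 2) {
      for (j in seq_len(i - 2)) {
        if (ddeg(i, j) < threshold_deg) found <- TRUE
      }
    }
    subtype[i] <- if (found) "re-capture" else "other"
  }
  list(overlap_status = status, subtype = subtype)
}

random_trial <- function(n, geometry = screen_geometry(), spread = NULL) {
  if (is.null(spread)) spread <- min(geometry$width_px, geometry$height_px) / 3
  cx <- (geometry$width_px - 1) / 2
  cy <- (geometry$height_px - 1) / 2
  make_fix(
    x = pmin(pmax(stats::rnorm(n, cx, spread), 0), geometry$width_px - 1),
    y = pmin(pmax(stats::rnorm(n, cy, spread), 0), geometry$height_px - 1)
  )
}

# Small two-group cohort for pipeline-level tests (fast).
small_cohort <- function(seed = 5, n_control = 4, n_patient = 4,
                         n_pictures = 4) {
  generate_cohort(cohort_params(n_control = n_control,
                                n_patient = n_patient,
                                n_pictures = n_pictures, seed = seed))
}
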