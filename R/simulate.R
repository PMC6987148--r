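# Truncated normal sampler via inverse-CDF; exact truncation, no clumping
# at the bounds.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Parameters for a synthetic FVE cohort
#'
#' Defaults emulate the behaviour of a neglect-patient and an age-matched
#' control cohort freely exploring 24 natural-scene pictures (12 originals
#' plus 12 mirrored versions, 7 s each, preceded by a central fixation
#' cross): per-half expected fixation counts per picture, a sequential
#' refixation process (each fixation is, with probability `p_cap`, placed
#' within `revisit_radius_deg` of the most recent earlier fixation of its
#' designated half and, with probability `p_rev`, within that radius of a
#' randomly chosen temporally distant earlier fixation of that half), and
#' truncated-normal fixation durations. Fresh placements draw from a
#' bivariate normal whose horizontal centre is the group's gaze bias,
#' truncated to the designated half, so the per-half counts and the bias
#' jointly reproduce the group's mean horizontal gaze position.
#'
#' @param n_control,n_patient Participants per group.
#' @param n_pictures Pictures per participant (default 24).
#' @param fix_per_half Named list of per-group `c(left=, right=)` expected
#'   fixation counts per picture (Poisson means).
#' @param gaze_bias_deg Named vector of per-group horizontal placement
#'   centres in degrees (the target mean gaze position).
#' @param p_cap,p_rev Named lists of per-group `c(left=, right=)`
#'   probabilities of capture-type and revisit-type placement.
#' @param duration_mean_ms,duration_sd_ms Per-group duration parameters
#'   before truncation to `[100, 2000]` ms.
#' @param revisit_radius_deg Placement radius for capture/revisit draws.
#' @param seed Integer RNG seed; regeneration with the same seed is
#'   bit-identical.
#' @return A list of class `fve_cohort_params`.
#' @export
cohort_params <- function(n_control = 20, n_patient = 15, n_pictures = 24,
                          fix_per_half = list(
                            control = c(left = 10.495, right = 11.012),
                            patient = c(left = 3.848, right = 13.859)),
                          gaze_bias_deg = c(control = 0.231, patient = 3.652),
                          p_cap = list(control = c(left = 0.18, right = 0.18),
                                       patient = c(left = 0.12, right = 0.30)),
                          p_rev = list(control = c(left = 0.20, right = 0.20),
                                       patient = c(left = 0.10, right = 0.25)),
                          duration_mean_ms = c(control = 133, patient = 178),
                          duration_sd_ms = c(control = 45, patient = 60),
                          revisit_radius_deg = 1,
                          seed = 1L) {
  for (g in c("control", "patient")) {
    stopifnot(
      all(fix_per_half[[g]] >= 0),
      all(p_cap[[g]] >= 0 & p_cap[[g]] <= 1),
      all(p_rev[[g]] >= 0 & p_rev[[g]] <= 1),
      all(p_cap[[g]] + p_rev[[g]] <= 1)
    )
  }
  stopifnot(n_control >= 0, n_patient >= 0, n_pictures >= 1,
            revisit_radius_deg > 0)
  structure(
    list(n_control = as.integer(n_control),
         n_patient = as.integer(n_patient),
         n_pictures = as.integer(n_pictures),
         fix_per_half = fix_per_half, gaze_bias_deg = gaze_bias_deg,
         p_cap = p_cap, p_rev = p_rev,
         duration_mean_ms = duration_mean_ms,
         duration_sd_ms = duration_sd_ms,
         revisit_radius_deg = revisit_radius_deg,
         seed = as.integer(seed)),
    class = "fve_cohort_params"
  )
}

#' Preset cohort parameters
#'
#' `"paper-cohort"` is the full two-group default; `"control"` and
#' `"neglect"` are single-group variants.
#'
#' @param preset One of `"control"`, `"neglect"`, `"paper-cohort"`.
#' @param seed RNG seed.
#' @param ... Overrides passed to [cohort_params()].
#' @return An `fve_cohort_params` object.
#' @export
preset_params <- function(preset = c("paper-cohort", "control", "neglect"),
                          seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "paper-cohort" = list(),
    "control" = list(n_patient = 0),
    "neglect" = list(n_control = 0)
  )
  do.call(cohort_params, c(args, list(seed = seed), list(...)))
}

place_in_half <- function(half, bias_deg, geometry) {
  ppd_h <- px_per_degree(geometry, "horizontal")
  half_w_deg <- geometry$h_deg / 2
  lo <- if (half == "left") -half_w_deg else 0
  hi <- if (half == "left") 0 else half_w_deg
  x_deg <- rtruncnorm(1, mean = bias_deg, sd = half_w_deg / 2, lo, hi)
  y_deg <- rtruncnorm(1, 0, geometry$v_deg / 4,
                      -geometry$v_deg / 2, geometry$v_deg / 2)
  c(x = (geometry$width_px - 1) / 2 + x_deg * ppd_h,
    y = (geometry$height_px - 1) / 2 +
      y_deg * px_per_degree(geometry, "vertical"))
}

place_near <- function(ref_xy, radius_deg, geometry) {
  # uniform in the angular disk, then clipped to the screen
  ang <- stats::runif(1, 0, 2 * pi)
  rad <- radius_deg * sqrt(stats::runif(1))
  x <- ref_xy[[1]] + cos(ang) * rad * px_per_degree(geometry, "horizontal")
  y <- ref_xy[[2]] + sin(ang) * rad * px_per_degree(geometry, "vertical")
  c(x = min(max(x, 0), geometry$width_px - 1),
    y = min(max(y, 0), geometry$height_px - 1))
}

#' Generate a synthetic FVE cohort
#'
#' Draws a seeded, fully reproducible fixation dataset under the generative
#' model described in [cohort_params()]. For each trial, per-half fixation
#' counts are Poisson draws around the group targets; the first fixation of
#' every picture starts near the screen centre (emulating the central
#' fixation cross); subsequent fixations are capture-type, revisit-type or
#' fresh truncated-normal placements within their designated half.
#' Durations are truncated normal within `[100, 2000]` ms; onsets
#' accumulate durations plus a nominal 30 ms saccade gap.
#'
#' The generator records its own placement decision per fixation in the
#' `gen_class` column (`"center"`, `"capture"`, `"revisit"`, `"base"`), so
#' classifier sensitivity can be measured against ground truth.
#'
#' @param params An [cohort_params()] object.
#' @param geometry A [screen_geometry()] object.
#' @return An [fve_dataset()] whose fixation tibble carries `gen_class`;
#'   the generating parameters are attached as attribute `"params"`.
#' @export
generate_cohort <- function(params = cohort_params(),
                            geometry = screen_geometry()) {
  stopifnot(inherits(params, "fve_cohort_params"))
  set.seed(params$seed)
  groups <- c(rep("control", params$n_control),
              rep("patient", params$n_patient))
  ids <- c(sprintf("ctrl_%02d", seq_len(params$n_control)),
           sprintf("pat_%02d", seq_len(params$n_patient)))
  pics <- sprintf("pic_%02d", seq_len(params$n_pictures))
  center <- c(x = (geometry$width_px - 1) / 2,
              y = (geometry$height_px - 1) / 2)
  ppd_h <- px_per_degree(geometry, "horizontal")
  out <- vector("list", length(ids) * length(pics))
  slot <- 0L
  for (p in seq_along(ids)) {
    g <- groups[p]
    mu <- params$fix_per_half[[g]]
    for (pic in pics) {
      n_l <- stats::rpois(1, mu[["left"]])
      n_r <- stats::rpois(1, mu[["right"]])
      n <- n_l + n_r
      slot <- slot + 1L
      if (n == 0) next
      halves <- sample(c(rep("left", n_l), rep("right", n_r)))
      xy <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
      gen_class <- character(n)
      for (i in seq_len(n)) {
        if (i == 1) {
          jit <- stats::rnorm(2, 0, 0.5) *
            c(ppd_h, px_per_degree(geometry, "vertical"))
          xy[i, ] <- c(min(max(center[["x"]] + jit[1], 0),
                           geometry$width_px - 1),
                       min(max(center[["y"]] + jit[2], 0),
                           geometry$height_px - 1))
          gen_class[i] <- "center"
          next
        }
        hv <- halves[i]
        u <- stats::runif(1)
        # refixation references are earlier fixations of the same designated
        # half, so the per-half count targets keep driving the spatial bias;
        # the forced central-cross fixation is not an exploration locus and
        # is never a reference
        same_half <- which(halves[seq_len(i - 1)] == hv &
                             gen_class[seq_len(i - 1)] != "center")
        prev_same <- if (length(same_half)) same_half[length(same_half)] else NA
        distant_same <- same_half[same_half != prev_same]
        if (u < params$p_cap[[g]][[hv]] && !is.na(prev_same)) {
          xy[i, ] <- place_near(xy[prev_same, ], params$revisit_radius_deg,
                                geometry)
          gen_class[i] <- "capture"
        } else if (u < params$p_cap[[g]][[hv]] + params$p_rev[[g]][[hv]] &&
                   length(distant_same)) {
          j <- if (length(distant_same) == 1) distant_same else
            sample(distant_same, 1)
          xy[i, ] <- place_near(xy[j, ], params$revisit_radius_deg, geometry)
          gen_class[i] <- "revisit"
        } else {
          xy[i, ] <- place_in_half(hv, params$gaze_bias_deg[[g]], geometry)
          gen_class[i] <- "base"
        }
      }
      dur <- rtruncnorm(n, params$duration_mean_ms[[g]],
                        params$duration_sd_ms[[g]], 100, 2000)
      onset <- cumsum(c(0, dur[-n] + 30))
      out[[slot]] <- tibble::tibble(
        participant_id = ids[p], group = g, picture_id = pic,
        onset_ms = onset, duration_ms = dur,
        x_px = xy[, 1], y_px = xy[, 2], gen_class = gen_class
      )
    }
  }
  ds <- fve_dataset(dplyr::bind_rows(out), geometry, params$n_pictures)
  attr(ds, "params") <- params
  ds
}
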