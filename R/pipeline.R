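anova_input <- function(metrics, metric_name, regions = c("left", "right")) {
  d <- metrics[metrics$picture_id == "ALL" & metrics$metric == metric_name &
                 metrics$region %in% regions, ]
  tibble::tibble(participant_id = d$participant_id, group = d$group,
                 half = d$region, value = d$value)
}

fmt_num <- function(x) formatC(x, digits = 4, format = "g")

#' Run the full FVE analysis pipeline
#'
#' Orchestrates duration filtering, the four conventional indicators, the
#' picture-wise and cumulative visual exploration areas, the
#' single/overlapping and capture/re-capture classification, the temporal
#' dynamics curves, and (when both groups are present with at least two
#' participants each) the group-comparison statistics. All results are
#' written as tidy CSVs plus a human-readable report; reruns on the same
#' input produce byte-identical metric files.
#'
#' @param dataset An [fve_dataset()], or `NULL` to read from `input`.
#' @param input Path to a fixation CSV (used when `dataset` is `NULL`).
#' @param output_dir Directory for result files (created if needed).
#' @param geometry A [screen_geometry()] object (used when reading CSV).
#' @param min_dur_ms,max_dur_ms Duration filter bounds.
#' @param radius_deg Foveal radius in degrees.
#' @param threshold_deg Capture/re-capture threshold in degrees.
#' @param consistent_thresholds See [classify_dataset()].
#' @param within_half See [area_fraction()].
#' @param k_max Temporal-dynamics prefix length.
#' @param bin_width_deg Histogram bin width.
#' @param export_masks Also write each participant's cumulative coverage
#'   raster as an ASCII PBM mask.
#' @return Invisibly, a list with all result tibbles and the paths written.
#' @export
run_analyze <- function(dataset = NULL, input = NULL, output_dir,
                        geometry = screen_geometry(),
                        min_dur_ms = 100, max_dur_ms = 2000,
                        radius_deg = 1, threshold_deg = 1,
                        consistent_thresholds = FALSE, within_half = FALSE,
                        k_max = 20, bin_width_deg = 2,
                        export_masks = FALSE) {
  if (is.null(dataset)) {
    if (is.null(input)) stop("provide a dataset or an input path",
                             call. = FALSE)
    dataset <- read_fixations(input, geometry)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- dataset$geometry
  filt <- filter_by_duration(dataset, min_dur_ms, max_dur_ms)
  ds <- filt$dataset

  conv <- conventional_metrics(ds)
  area <- picture_wise_area(ds, within_half)
  cum_area <- cumulative_area(ds, within_half = within_half)
  classified <- classify_dataset(ds, radius_deg, threshold_deg,
                                 consistent_thresholds)
  classes <- class_metrics(classified)
  dynamics <- temporal_dynamics(classified, k_max)
  hist_tbl <- dplyr::group_modify(
    dplyr::group_by(ds$fixations, .data$group),
    function(d, key) horizontal_histogram(d, geom, bin_width_deg)
  )
  hist_tbl <- dplyr::ungroup(hist_tbl)

  paths <- c(
    conventional = file.path(output_dir, "conventional_metrics.csv"),
    area = file.path(output_dir, "area_metrics.csv"),
    cumulative = file.path(output_dir, "cumulative_area.csv"),
    classes = file.path(output_dir, "class_metrics.csv"),
    dynamics = file.path(output_dir, "dynamics.csv"),
    histogram = file.path(output_dir, "histogram.csv")
  )
  write_metrics(conv, paths[["conventional"]])
  write_metrics(area, paths[["area"]])
  write_metrics(cum_area, paths[["cumulative"]])
  write_metrics(classes, paths[["classes"]])
  readr::write_csv(dynamics, paths[["dynamics"]], progress = FALSE)
  readr::write_csv(hist_tbl, paths[["histogram"]], progress = FALSE)

  stats_out <- NULL
  groups_n <- table(unique(ds$fixations[c("participant_id", "group")])$group)
  if (length(groups_n) == 2 && all(groups_n >= 2)) {
    stats_out <- compare_groups(conv, area, cum_area, classes)
    readr::write_csv(stats_out$anova, file.path(output_dir, "stats_anova.csv"),
                     progress = FALSE)
    readr::write_csv(stats_out$ttests, file.path(output_dir, "stats_ttests.csv"),
                     progress = FALSE)
    readr::write_csv(stats_out$posthoc, file.path(output_dir, "stats_posthoc.csv"),
                     progress = FALSE)
    writeLines(stats_out$report, file.path(output_dir, "report.txt"))
  }
  if (export_masks) {
    for (pid in unique(ds$fixations$participant_id)) {
      ras <- rasterize(ds$fixations[ds$fixations$participant_id == pid, ],
                       geom)
      write_mask(ras, file.path(output_dir, paste0("mask_", pid, ".pbm")))
    }
  }

  params <- attr(dataset, "params")
  log_lines <- c(
    paste0("fovarea ", as.character(utils::packageVersion("fovarea"))),
    paste0("foveal radius: ", radius_deg, " deg = ",
           foveal_radius_px(geom), " px"),
    paste0("duration filter: [", min_dur_ms, ", ", max_dur_ms, "] ms; ",
           "excluded fraction: ", fmt_num(filt$excluded_fraction)),
    paste0("fixations analysed: ", nrow(ds$fixations)),
    if (!is.null(params)) paste0("generator seed: ", params$seed)
  )
  writeLines(log_lines, file.path(output_dir, "log.txt"))

  invisible(list(
    dataset = ds, classified = classified,
    conventional = conv, area = area, cumulative = cum_area,
    classes = classes, dynamics = dynamics, histogram = hist_tbl,
    stats = stats_out, excluded_fraction = filt$excluded_fraction,
    paths = paths, output_dir = output_dir
  ))
}

#' Group-comparison statistics over computed metrics tables
#'
#' Replicates the inferential pipeline on per-participant averages
#' (`picture_id == "ALL"`): two-sided Welch t-tests for mean gaze position,
#' leftmost fixation and total exploration areas; 2 x 2 mixed ANOVAs
#' (group x screen half) for per-half fixation counts, cumulative
#' durations, exploration areas and overlap proportion; a 2 x 2 x 2 mixed
#' ANOVA (group x half x fixation category) for single vs. overlapping
#' counts; and a 2 x 2 (group x overlap category) for capture vs.
#' re-capture counts. Each ANOVA's cells get Bonferroni-corrected post hoc
#' t-tests.
#'
#' @param conventional,area,cumulative,classes Metrics tibbles produced by
#'   [conventional_metrics()], [picture_wise_area()], [cumulative_area()]
#'   and [class_metrics()].
#' @return List with tibbles `ttests`, `anova`, `posthoc` and a character
#'   vector `report`.
#' @export
compare_groups <- function(conventional, area, cumulative, classes) {
  all_rows <- function(tbl, metric_name, region) {
    tbl[tbl$picture_id == "ALL" & tbl$metric == metric_name &
          tbl$region == region, ]
  }
  by_group <- function(d) split(d$value, d$group)

  ttests <- list()
  for (spec in list(
    list(tbl = conventional, metric = "mean_gaze_deg", region = "total"),
    list(tbl = conventional, metric = "leftmost_deg", region = "total"),
    list(tbl = area, metric = "area_pct", region = "total"),
    list(tbl = cumulative, metric = "cum_area_pct", region = "total")
  )) {
    d <- all_rows(spec$tbl, spec$metric, spec$region)
    s <- by_group(d)
    if (length(s) != 2) next
    res <- welch_t(s$control, s$patient)
    res$metric <- spec$metric
    ttests[[length(ttests) + 1]] <- res
  }
  ttests <- dplyr::bind_rows(ttests)

  anovas <- list()
  posthocs <- list()
  add_anova <- function(name, data, within) {
    data <- data[stats::complete.cases(data), ]
    an <- mixed_anova(data, within = within)
    an$analysis <- name
    ph <- bonferroni_posthoc(data, within = within)
    ph$analysis <- name
    anovas[[length(anovas) + 1]] <<- an
    posthocs[[length(posthocs) + 1]] <<- ph
  }

  add_anova("n_fix_2x2", anova_input(conventional, "n_fix"), "half")
  add_anova("cum_dur_2x2", anova_input(conventional, "cum_dur_ms"), "half")
  add_anova("area_2x2", anova_input(area, "area_pct"), "half")
  add_anova("cum_area_2x2", anova_input(cumulative, "cum_area_pct"), "half")
  add_anova("prop_overlap_2x2", anova_input(classes, "prop_overlap"), "half")

  singles <- anova_input(classes, "n_single")
  singles$category <- "single"
  overlaps <- anova_input(classes, "n_overlap")
  overlaps$category <- "overlapping"
  add_anova("class_counts_2x2x2", dplyr::bind_rows(singles, overlaps),
            c("half", "category"))

  cap <- classes[classes$picture_id == "ALL" & classes$region == "total" &
                   classes$metric %in% c("n_capture", "n_recapture"), ]
  cap_d <- tibble::tibble(participant_id = cap$participant_id,
                          group = cap$group,
                          category = sub("n_", "", cap$metric),
                          value = cap$value)
  an <- mixed_anova(cap_d, within = "category")
  an$analysis <- "capture_recapture_2x2"
  anovas[[length(anovas) + 1]] <- an
  ph <- bonferroni_posthoc(cap_d, within = "category")
  ph$analysis <- "capture_recapture_2x2"
  posthocs[[length(posthocs) + 1]] <- ph

  anova_tbl <- dplyr::bind_rows(anovas)
  posthoc_tbl <- dplyr::bind_rows(posthocs)

  report <- c(
    "Group comparison report",
    "=======================",
    "",
    "Welch t-tests (control vs patient):",
    sprintf("  %-14s t(%s) = %s, p = %s, r = %s",
            ttests$metric, fmt_num(ttests$df), fmt_num(ttests$statistic),
            fmt_num(ttests$p_value), fmt_num(ttests$cohens_r)),
    "",
    "Mixed ANOVAs:",
    sprintf("  %-22s %-28s F(%d, %d) = %s, p = %s, partial eta2 = %s",
            anova_tbl$analysis, anova_tbl$effect, anova_tbl$df1,
            anova_tbl$df2, fmt_num(anova_tbl$statistic),
            fmt_num(anova_tbl$p_value), fmt_num(anova_tbl$pes))
  )
  list(ttests = ttests, anova = anova_tbl, posthoc = posthoc_tbl,
       report = report)
}

#' Figures for the main analyses
#'
#' Produces, from the result list of [run_analyze()]: a per-group
#' horizontal fixation histogram with the mean cumulative per-half
#' exploration areas annotated; capture/re-capture temporal-dynamics
#' curves with standard-error ribbons; and a fixation/coverage overlay
#' (fixation centres plus foveal disks) for one example trial. Every
#' plotted value comes from the tidy CSVs `run_analyze()` already wrote.
#'
#' @param results List returned by [run_analyze()].
#' @param output_dir Directory for figure files (defaults to the analysis
#'   output directory).
#' @return Invisibly, the paths of the figures written.
#' @export
run_plots <- function(results, output_dir = results$output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  hist_tbl <- results$histogram
  cum <- results$cumulative[results$cumulative$region != "total", ]
  cum_mean <- dplyr::summarise(
    dplyr::group_by(cum, .data$group, .data$region),
    value = mean(.data$value), .groups = "drop")
  if (nrow(hist_tbl)) {
    lab <- sprintf("%s half: %.1f%%", cum_mean$region, cum_mean$value)
    p1 <- ggplot2::ggplot(hist_tbl) +
      ggplot2::geom_rect(ggplot2::aes(xmin = .data$bin_lo,
                                      xmax = .data$bin_hi,
                                      ymin = 0, ymax = .data$count),
                         fill = "grey40", colour = "white",
                         linewidth = 0.2) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::facet_wrap(~group, ncol = 1, scales = "free_y") +
      ggplot2::labs(x = "horizontal position (deg from centre)",
                    y = "fixations",
                    title = "Spatial distribution of fixations",
                    subtitle = paste(
                      sprintf("%s: %s", cum_mean$group, lab),
                      collapse = "; ")) +
      ggplot2::theme_minimal()
    f1 <- file.path(output_dir, "fig_histogram.png")
    ggplot2::ggsave(f1, p1, width = 7, height = 5, dpi = 120)
    paths <- c(paths, f1)
  }

  dyn <- results$dynamics
  if (!is.null(dyn) && nrow(dyn)) {
    p2 <- ggplot2::ggplot(dyn, ggplot2::aes(x = .data$k, y = .data$mean_pct,
                                            colour = .data$group,
                                            fill = .data$group)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_pct - .data$sem,
                                        ymax = .data$mean_pct + .data$sem),
                           alpha = 0.25, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~subtype) +
      ggplot2::labs(x = "fixation rank k", y = "mean % among first k",
                    title = "Temporal dynamics of capture / re-capture") +
      ggplot2::theme_minimal()
    f2 <- file.path(output_dir, "fig_dynamics.png")
    ggplot2::ggsave(f2, p2, width = 7, height = 4, dpi = 120)
    paths <- c(paths, f2)
  }

  fix <- results$dataset$fixations
  if (nrow(fix)) {
    geom <- results$dataset$geometry
    first_trial <- fix[fix$participant_id == fix$participant_id[1] &
                         fix$picture_id == fix$picture_id[1], ]
    r_px <- foveal_radius_px(geom)
    circ <- do.call(rbind, lapply(seq_len(nrow(first_trial)), function(i) {
      th <- seq(0, 2 * pi, length.out = 60)
      data.frame(id = i, x = first_trial$x_px[i] + r_px * cos(th),
                 y = first_trial$y_px[i] + r_px * sin(th))
    }))
    p3 <- ggplot2::ggplot() +
      ggplot2::geom_polygon(data = circ,
                            ggplot2::aes(.data$x, .data$y, group = .data$id),
                            fill = "gold", alpha = 0.35) +
      ggplot2::geom_path(data = first_trial,
                         ggplot2::aes(.data$x_px, .data$y_px),
                         colour = "grey50") +
      ggplot2::geom_point(data = first_trial,
                          ggplot2::aes(.data$x_px, .data$y_px)) +
      ggplot2::scale_y_reverse(limits = c(geom$height_px - 1, 0)) +
      ggplot2::coord_fixed(xlim = c(0, geom$width_px - 1)) +
      ggplot2::labs(title = "Example trial: fixations and foveal coverage",
                    x = "x (px)", y = "y (px)") +
      ggplot2::theme_minimal()
    f3 <- file.path(output_dir, "fig_overlay.png")
    ggplot2::ggsave(f3, p3, width = 7, height = 5.5, dpi = 120)
    paths <- c(paths, f3)
  }
  invisible(paths)
}
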