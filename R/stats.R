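#' Cohen's r from a t statistic
#'
#' `r = sqrt(t^2 / (t^2 + df))`, the effect-size correlation associated
#' with a t-test.
#'
#' @param t t statistic.
#' @param df Degrees of freedom (possibly fractional, e.g. Welch).
#' @return Effect size in `[0, 1]`.
#' @examples
#' cohens_r_from_t(-7.275, 16.686)
#' @export
cohens_r_from_t <- function(t, df) {
  sqrt(t^2 / (t^2 + df))
}

#' Welch two-sample t-test with effect size
#'
#' Two-sided independent-samples t-test. The default does not assume equal
#' variances (Welch-Satterthwaite degrees of freedom); pass
#' `student = TRUE` for the pooled-variance Student test.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param student Use the pooled-variance Student t-test instead of Welch.
#' @return A one-row tibble: `statistic` (t), `df`, `p_value`, `cohens_r`,
#'   `mean_a`, `mean_b`.
#' @export
welch_t <- function(sample_a, sample_b, student = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0 &&
      mean(sample_a) == mean(sample_b)) {
    return(tibble::tibble(
      statistic = 0,
      df = length(sample_a) + length(sample_b) - 2,
      p_value = 1, cohens_r = 0,
      mean_a = mean(sample_a), mean_b = mean(sample_b)
    ))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = student)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    cohens_r = cohens_r_from_t(unname(ht$statistic), unname(ht$parameter)),
    mean_a = mean(sample_a), mean_b = mean(sample_b)
  )
}

check_balanced <- function(data, id, within) {
  cells <- interaction(data[within], drop = FALSE)
  tab <- table(data[[id]], cells)
  bad <- rownames(tab)[apply(tab != 1, 1, any)]
  if (length(bad)) {
    stop("unbalanced design: participant(s) without exactly one value per ",
         "within-cell: ", paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Balanced split-plot (mixed-design) ANOVA
#'
#' Fits the classic repeated-measures sums-of-squares decomposition for a
#' balanced design with one between-subjects factor and zero, one or two
#' within-subjects factors, via [stats::aov()] with the appropriate
#' `Error()` strata. This covers 2 x 2 (group x screen half) and
#' 2 x 2 x 2 (group x screen half x fixation category) analyses.
#' Effect size is partial eta-squared,
#' `SS_effect / (SS_effect + SS_error)` with the error term of the
#' effect's own stratum; generalized eta-squared is also reported.
#'
#' With no within factor the fit reduces to a one-way between ANOVA.
#'
#' @param data Long-format data frame with one row per participant x
#'   within-cell.
#' @param dv Name of the response column.
#' @param between Name of the between-subjects factor column.
#' @param within Character vector of 0-2 within-subjects factor columns.
#' @param id Name of the participant identifier column.
#' @return Tibble with one row per effect: `effect`, `df1`, `df2`,
#'   `statistic` (F), `p_value`, `pes` (partial eta-squared), `ges`, `ss`,
#'   `ss_error`.
#' @export
mixed_anova <- function(data, dv = "value", between = "group",
                        within = character(), id = "participant_id") {
  data <- as.data.frame(data)
  for (v in c(between, within, id)) data[[v]] <- factor(data[[v]])
  if (any(table(unique(data[c(id, between)])[[id]]) > 1)) {
    stop("participants must belong to exactly one between-group",
         call. = FALSE)
  }
  if (length(unique(data[[between]])) < 2 ||
      any(table(unique(data[c(id, between)])[[between]]) < 2)) {
    stop("need at least 2 participants per group", call. = FALSE)
  }
  if (length(within) > 0) check_balanced(data, id, within)
  fixed <- paste(c(between, within), collapse = " * ")
  form <- if (length(within) == 0) {
    stats::as.formula(paste(dv, "~", fixed))
  } else {
    stats::as.formula(paste0(
      dv, " ~ ", fixed, " + Error(", id, "/(",
      paste(within, collapse = " * "), "))"))
  }
  fit <- stats::aov(form, data = data)
  strata <- if (inherits(fit, "aovlist")) summary(fit) else list(summary(fit))
  rows <- list()
  ss_error_all <- 0
  for (s in strata) {
    tab <- as.data.frame(if (is.list(s)) s[[1]] else s)
    nm <- trimws(rownames(tab))
    resid_i <- which(nm == "Residuals")
    ss_err <- if (length(resid_i)) tab[resid_i, "Sum Sq"] else NA_real_
    df_err <- if (length(resid_i)) tab[resid_i, "Df"] else NA_real_
    ss_error_all <- ss_error_all + if (length(resid_i)) ss_err else 0
    eff_i <- setdiff(seq_len(nrow(tab)), resid_i)
    for (i in eff_i) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = gsub(" ", "", nm[i], fixed = TRUE),
        df1 = tab[i, "Df"], df2 = df_err,
        statistic = tab[i, "F value"], p_value = tab[i, "Pr(>F)"],
        ss = tab[i, "Sum Sq"], ss_error = ss_err
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$effect <- gsub(":", " x ", out$effect, fixed = TRUE)
  out$pes <- out$ss / (out$ss + out$ss_error)
  # generalized eta^2: effect SS over effect SS plus all error SS
  out$ges <- out$ss / (out$ss + ss_error_all)
  out[c("effect", "df1", "df2", "statistic", "p_value", "pes", "ges",
        "ss", "ss_error")]
}

#' Bonferroni-corrected post hoc t-tests over design cells
#'
#' All pairwise comparisons among the cells of a between x within design.
#' Pairs within the same between-group level are paired t-tests (matched by
#' participant); pairs across groups are independent Welch t-tests.
#' Adjusted p-values are `min(1, m * p)` with `m` the number of pairs.
#'
#' @inheritParams mixed_anova
#' @return Tibble with columns `cell_a`, `cell_b`, `type` (`"paired"` or
#'   `"independent"`), `statistic`, `df`, `p_raw`, `p_adj`, `n_comparisons`.
#' @export
bonferroni_posthoc <- function(data, dv = "value", between = "group",
                               within = character(),
                               id = "participant_id") {
  data <- as.data.frame(data)
  cell_cols <- c(between, within)
  cell_of <- interaction(data[cell_cols], sep = ".", drop = TRUE)
  cells <- levels(cell_of)
  if (length(cells) < 2) {
    return(tibble::tibble(cell_a = character(), cell_b = character(),
                          type = character(), statistic = numeric(),
                          df = numeric(), p_raw = numeric(),
                          p_adj = numeric(), n_comparisons = integer()))
  }
  pairs <- utils::combn(cells, 2)
  m <- ncol(pairs)
  grp_of_cell <- vapply(cells, function(cl) {
    as.character(data[[between]][cell_of == cl][1])
  }, character(1))
  rows <- lapply(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    da <- data[cell_of == a, ]; db <- data[cell_of == b, ]
    run_t <- function(expr) {
      # zero-variance cells (possible in tiny or degenerate designs) make
      # the t undefined; report NA rather than aborting the family
      tryCatch(expr, error = function(e) NULL)
    }
    if (grp_of_cell[[a]] == grp_of_cell[[b]]) {
      merged <- merge(da[c(id, dv)], db[c(id, dv)], by = id)
      ht <- run_t(stats::t.test(merged[[paste0(dv, ".x")]],
                                merged[[paste0(dv, ".y")]], paired = TRUE))
      type <- "paired"
    } else {
      ht <- run_t(stats::t.test(da[[dv]], db[[dv]], var.equal = FALSE))
      type <- "independent"
    }
    tibble::tibble(cell_a = a, cell_b = b, type = type,
                   statistic = if (is.null(ht)) NA_real_ else
                     unname(ht$statistic),
                   df = if (is.null(ht)) NA_real_ else unname(ht$parameter),
                   p_raw = if (is.null(ht)) NA_real_ else ht$p.value,
                   p_adj = if (is.null(ht)) NA_real_ else
                     min(1, m * ht$p.value),
                   n_comparisons = m)
  })
  dplyr::bind_rows(rows)
}
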