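# Hand-computed split-plot sums of squares for a balanced design with one
# between factor and one within factor, straight from the textbook formulas.
splitplot_ss <- function(d) {
  gm <- mean(d$value)
  b <- length(unique(d$half))
  subj <- tapply(d$value, d$participant_id, mean)
  grp_of <- tapply(as.character(d$group), d$participant_id, `[`, 1)
  grp_means <- tapply(d$value, d$group, mean)
  half_means <- tapply(d$value, d$half, mean)
  cell_means <- tapply(d$value, list(d$group, d$half), mean)
  n_per_grp <- table(grp_of)
  ss_total <- sum((d$value - gm)^2)
  ss_between_subj <- b * sum((subj - gm)^2)
  ss_group <- b * sum(n_per_grp * (grp_means[names(n_per_grp)] - gm)^2)
  ss_subj_err <- ss_between_subj - ss_group
  n_subj <- length(subj)
  ss_half <- n_subj * sum((half_means - gm)^2)
  ss_int <- 0
  for (gname in rownames(cell_means)) {
    for (hname in colnames(cell_means)) {
      ss_int <- ss_int + n_per_grp[[gname]] *
        (cell_means[gname, hname] - grp_means[[gname]] -
           half_means[[hname]] + gm)^2
    }
  }
  ss_within_err <- ss_total - ss_between_subj - ss_half - ss_int
  list(group = ss_group, half = ss_half, int = ss_int,
       subj_err = ss_subj_err, within_err = ss_within_err,
       total = ss_total)
}

toy_mixed <- function(seed = 2, n_per_group = 4, sd = 1) {
  set.seed(seed)
  cells <- expand.grid(group = c("control", "patient"),
                       half = c("left", "right"),
                       stringsAsFactors = FALSE)
  effects <- c(2, 5, 4, 12)  # cell means
  out <- list()
  for (i in seq_len(nrow(cells))) {
    for (s in seq_len(n_per_group)) {
      out[[length(out) + 1]] <- tibble::tibble(
        participant_id = paste0(cells$group[i], s),
        group = cells$group[i], half = cells$half[i],
        value = effects[i] + rnorm(1, 0, sd))
    }
  }
  dplyr::bind_rows(out)
}

test_that("Welch t-test reproduces t.test and the effect-size formula", {
  a <- c(1.2, 3.4, 2.2, 4.8)
  b <- c(5.1, 6.0, 7.2)
  res <- welch_t(a, b)
  ref <- t.test(a, b)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$cohens_r,
               sqrt(res$statistic^2 / (res$statistic^2 + res$df)))
  # antisymmetry: swapping samples flips t, keeps p and r
  swapped <- welch_t(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(swapped$cohens_r, res$cohens_r)
  # degenerate equal constant samples
  degen <- welch_t(c(2, 2, 2), c(2, 2))
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_value, 1)
  expect_equal(degen$cohens_r, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("the r-from-t conversion is exact on known values", {
  expect_equal(cohens_r_from_t(2, 4), sqrt(4 / 8))
  expect_equal(cohens_r_from_t(-2, 4), sqrt(4 / 8))
  expect_equal(cohens_r_from_t(0, 10), 0)
})

test_that("split-plot ANOVA matches hand-computed sums of squares", {
  d <- toy_mixed()
  fit <- mixed_anova(d, within = "half")
  ss <- splitplot_ss(d)
  get <- function(eff) fit[fit$effect == eff, ]
  expect_equal(get("group")$ss, ss$group)
  expect_equal(get("half")$ss, ss$half)
  expect_equal(get("group x half")$ss, ss$int)
  expect_equal(get("group")$ss_error, ss$subj_err)
  expect_equal(get("half")$ss_error, ss$within_err)
  # F ratios and dfs
  n <- length(unique(d$participant_id))
  expect_equal(get("group")$df1, 1)
  expect_equal(get("group")$df2, n - 2)
  expect_equal(get("group")$statistic,
               (ss$group / 1) / (ss$subj_err / (n - 2)))
  expect_equal(get("group x half")$statistic,
               ss$int / (ss$within_err / (n - 2)))
  # partial eta squared definition
  expect_equal(get("group x half")$pes, ss$int / (ss$int + ss$within_err))
  # SS decomposition is exhaustive
  expect_equal(ss$group + ss$half + ss$int + ss$subj_err + ss$within_err,
               ss$total)
  expect_equal(sum(fit$ss) + sum(unique(fit$ss_error)), ss$total)
})

test_that("zero-error cell-mean data decompose exactly", {
  cells <- expand.grid(group = c("control", "patient"),
                       half = c("left", "right"),
                       stringsAsFactors = FALSE)
  effects <- c(2, 5, 4, 12)
  d <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    tibble::tibble(participant_id = paste0(cells$group[i], 1:3),
                   group = cells$group[i], half = cells$half[i],
                   value = effects[i])
  }))
  fit <- mixed_anova(d, within = "half")
  ss <- splitplot_ss(d)
  expect_equal(fit$ss[fit$effect == "group"], ss$group)
  expect_equal(fit$ss[fit$effect == "half"], ss$half)
  expect_equal(fit$ss_error, rep(0, 3), tolerance = 1e-10)
  # within-factor with identical values across levels has zero SS
  d2 <- d
  d2$value <- ifelse(d2$group == "patient", 10, 2)
  fit2 <- mixed_anova(d2, within = "half")
  expect_equal(fit2$ss[fit2$effect == "half"], 0, tolerance = 1e-12)
})

test_that("with no within factor the fit reduces to a one-way ANOVA", {
  set.seed(8)
  d <- tibble::tibble(
    participant_id = paste0("s", 1:12),
    group = rep(c("control", "patient"), each = 6),
    value = rnorm(12, rep(c(0, 1), each = 6)))
  fit <- mixed_anova(d)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(fit$statistic[fit$effect == "group"],
               unname(tt$statistic)^2)
  expect_equal(fit$df1[fit$effect == "group"], 1)
  expect_equal(fit$df2[fit$effect == "group"], 10)
})

test_that("three-factor designs return the full effect table", {
  set.seed(19)
  d <- tidyr::expand_grid(
    participant_id = paste0("s", 1:8),
    half = c("left", "right"),
    category = c("single", "overlapping"))
  d$group <- ifelse(d$participant_id %in% paste0("s", 1:4),
                    "control", "patient")
  d$value <- rnorm(nrow(d), 5)
  fit <- mixed_anova(d, within = c("half", "category"))
  expect_setequal(
    fit$effect,
    c("group", "half", "group x half", "category", "group x category",
      "half x category", "group x half x category"))
  expect_true(all(fit$pes >= 0 & fit$pes <= 1))
  expect_true(all(fit$df1 == 1))
  expect_true(all(fit$df2 == 6))
})

test_that("unbalanced or malformed designs are rejected with the culprit", {
  d <- toy_mixed()
  expect_error(mixed_anova(d[-1, ], within = "half"), "control1")
  bad <- d
  bad$group[1] <- "patient"
  expect_error(mixed_anova(bad, within = "half"), "exactly one")
  tiny <- d[d$participant_id %in% c("control1", "patient1", "patient2"), ]
  expect_error(mixed_anova(tiny, within = "half"), "2 participants")
})

test_that("Bonferroni post hocs enumerate pairs, pick test types, cap at 1", {
  d <- toy_mixed(seed = 3)
  ph <- bonferroni_posthoc(d, within = "half")
  expect_identical(nrow(ph), 6L)
  expect_true(all(ph$n_comparisons == 6))
  expect_equal(ph$p_adj, pmin(1, 6 * ph$p_raw))
  # same group across halves -> paired; across groups -> independent
  same_grp <- ph$cell_a == "control.left" & ph$cell_b == "control.right"
  expect_identical(ph$type[same_grp], "paired")
  cross <- ph$cell_a == "control.left" & ph$cell_b == "patient.left"
  expect_identical(ph$type[cross], "independent")
  # two cells -> a single uncorrected comparison
  ph2 <- bonferroni_posthoc(d[d$half == "left", ])
  expect_identical(nrow(ph2), 1L)
  expect_equal(ph2$p_adj, ph2$p_raw)
  # single cell -> empty table
  ph1 <- bonferroni_posthoc(d[d$half == "left" & d$group == "control", ])
  expect_identical(nrow(ph1), 0L)
})
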