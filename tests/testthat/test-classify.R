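deg_fix <- function(xd, yd, g = screen_geometry()) {
  # place fixations by degree offsets from the picture centre
  make_fix(x = xd * px_per_degree(g, "horizontal") + (g$width_px - 1) / 2,
           y = yd * px_per_degree(g, "vertical") + (g$height_px - 1) / 2)
}

test_that("single vs overlapping follows the strict 2-radius rule", {
  g <- screen_geometry()
  one <- classify_overlap(deg_fix(0, 0), g)
  expect_identical(one$overlap_status, "single")
  coincident <- classify_overlap(deg_fix(c(3, 3), c(0, 0)), g)
  expect_identical(coincident$overlap_status, rep("overlapping", 2))
  # tangent disks (centres exactly 2 deg apart) have zero-area intersection
  # and stay single; anything strictly closer overlaps. 10 px/deg square
  # geometry keeps the distances exact in floating point.
  sq <- screen_geometry(200, 200, 20, 20)
  tangent <- classify_overlap(make_fix(c(80, 100), c(100, 100)), sq)
  expect_identical(tangent$overlap_status, rep("single", 2))
  close <- classify_overlap(make_fix(c(81, 100), c(100, 100)), sq)
  expect_identical(close$overlap_status, rep("overlapping", 2))
})

test_that("a synthesized 19-fixation trial yields 4 single and 15 overlapping", {
  g <- screen_geometry()
  # 5 clusters of 3 coincident-ish fixations (15 overlapping) plus 4
  # isolated fixations at least 2 deg from everything else
  clusters <- c(-10, -5, 0, 5, 10)
  xd <- c(rep(clusters, each = 3) + rep(c(0, 0.3, -0.3), 5),
          c(-12, -7, 3, 8))
  yd <- c(rep(-5, 15), rep(5, 4))
  trial <- classify_overlap(deg_fix(xd, yd), g)
  expect_identical(sum(trial$overlap_status == "single"), 4L)
  expect_identical(sum(trial$overlap_status == "overlapping"), 15L)
})

test_that("capture needs the immediate predecessor, re-capture a distant one", {
  g <- screen_geometry()
  # B coincident with its predecessor A -> capture
  ab <- classify_capture_recapture(
    classify_overlap(deg_fix(c(0, 0.2), c(0, 0)), g), g)
  # A itself overlaps B but has no prior fixation, so it is "other"
  expect_identical(ab$subtype, c("other", "capture"))
  # C returns to A after an excursion to far-away B -> re-capture
  abc <- classify_capture_recapture(
    classify_overlap(deg_fix(c(0, 8, 0.2), c(0, 0, 0)), g), g)
  expect_identical(abc$subtype[3], "re-capture")
  # an overlapping fixation whose only near neighbour lies in the future
  # is "other", not silently forced into a class
  fut <- classify_capture_recapture(
    classify_overlap(deg_fix(c(0, 8, 0.2), c(0, 0, 0))[c(1, 3, 2), ], g), g)
  expect_identical(fut$subtype[1], "other")
})

test_that("labels match the brute-force oracle on random trials", {
  g <- screen_geometry()
  set.seed(77)
  for (rep in 1:10) {
    fix <- random_trial(20, g, spread = 120)
    got <- classify_capture_recapture(classify_overlap(fix, g), g)
    want <- naive_classify(fix, g)
    expect_identical(got$overlap_status, want$overlap_status)
    expect_identical(got$subtype, want$subtype)
  }
})

test_that("overlap detection is time-symmetric, subtype labels are not", {
  g <- screen_geometry()
  set.seed(31)
  fix <- random_trial(15, g, spread = 100)
  fwd <- classify_overlap(fix, g)
  rev_fix <- fix[15:1, ]
  rev_fix$order_index <- 1:15
  rev_fix$onset_ms <- sort(rev_fix$onset_ms)
  bwd <- classify_overlap(rev_fix, g)
  expect_identical(fwd$overlap_status, rev(bwd$overlap_status))
  # asymmetric example: A,B close pair -> forward labels B capture, reversed
  # labels A capture; the label sequence differs
  ab <- deg_fix(c(0, 0.2), c(0, 0))
  fwd_ab <- classify_capture_recapture(classify_overlap(ab, g), g)
  ba <- ab[2:1, ]
  ba$order_index <- 1:2
  bwd_ab <- classify_capture_recapture(classify_overlap(ba, g), g)
  expect_false(identical(fwd_ab$subtype, rev(bwd_ab$subtype)))
})

test_that("partition identities hold for every region on random trials", {
  g <- screen_geometry()
  set.seed(1234)
  for (rep in 1:25) {
    fix <- random_trial(sample(2:25, 1), g, spread = 150)
    cc <- class_counts(
      classify_capture_recapture(classify_overlap(fix, g), g), g)
    expect_equal(cc$n_single + cc$n_overlap, cc$n_fix)
    expect_equal(cc$n_capture + cc$n_recapture + cc$n_other, cc$n_overlap)
    expect_equal(cc$n_fix[cc$region == "left"] +
                   cc$n_fix[cc$region == "right"],
                 cc$n_fix[cc$region == "total"])
  }
})

test_that("raising the revisit threshold never loses capture/re-capture", {
  g <- screen_geometry()
  set.seed(404)
  for (rep in 1:10) {
    fix <- random_trial(15, g, spread = 100)
    ov <- classify_overlap(fix, g)
    n_cr <- vapply(c(0.5, 1, 2), function(th) {
      sub <- classify_capture_recapture(ov, g, threshold_deg = th)$subtype
      sum(sub %in% c("capture", "re-capture"))
    }, numeric(1))
    expect_true(all(diff(n_cr) >= 0))
    # at threshold = 2r, "other" survives only when all near neighbours
    # are in the future
    full <- classify_capture_recapture(ov, g, threshold_deg = 2)
    xy <- cbind(full$x_px / px_per_degree(g, "horizontal"),
                full$y_px / px_per_degree(g, "vertical"))
    for (i in which(full$subtype == "other")) {
      if (i == 1) next
      past <- sqrt(rowSums((xy[seq_len(i - 1), , drop = FALSE] -
                              matrix(xy[i, ], i - 1, 2, byrow = TRUE))^2))
      expect_true(all(past >= 2))
    }
  }
})

test_that("overlap proportion is the overlap-to-single ratio with NA at 0", {
  cc <- tibble::tibble(region = c("left", "right", "total"),
                       n_single = c(5, 4, 0), n_overlap = c(0, 15, 15))
  expect_equal(overlap_proportion(cc, "left"), 0)
  expect_equal(overlap_proportion(cc, "right"), 3.75)
  expect_true(is.na(overlap_proportion(cc, "total")))
})

test_that("temporal dynamics match closed forms and a brute-force recount", {
  g <- screen_geometry()
  # all fixations coincident: every fixation after the first is a capture,
  # so the capture curve is 100 (k-1)/k and re-capture stays 0
  co <- make_fix(rep(600, 8), rep(450, 8))
  ds <- classify_dataset(make_dataset(co, g))
  dyn <- temporal_dynamics(ds, k_max = 8)
  cap <- dyn[dyn$subtype == "capture", ]
  expect_equal(cap$mean_pct, 100 * (0:7) / (1:8))
  expect_equal(dyn$mean_pct[dyn$subtype == "re-capture"], rep(0, 8))
  expect_equal(cap$mean_pct[1], 0)

  # random cohort: group means equal an explicit per-picture recount
  cohort <- classify_dataset(small_cohort(seed = 21, n_control = 2,
                                          n_patient = 2, n_pictures = 3))
  dyn2 <- temporal_dynamics(cohort, k_max = 6)
  fix <- cohort$fixations
  recount <- function(grp, what, k) {
    per_part <- vapply(
      split(fix[fix$group == grp, ],
            fix$participant_id[fix$group == grp]),
      function(pf) {
        vals <- vapply(split(pf, pf$picture_id), function(tf) {
          tf <- tf[order(tf$order_index), ]
          if (nrow(tf) < 1) return(NA_real_)
          kk <- min(k, nrow(tf))
          if (kk < k) return(NA_real_)
          100 * sum(tf$subtype[1:k] == what) / k
        }, numeric(1))
        mean(vals, na.rm = TRUE)
      }, numeric(1))
    mean(per_part)
  }
  for (k in c(1, 3, 6)) {
    # all pictures in this small cohort have >= 6 fixations, so the
    # prefix-contribution rule reduces to a plain recount
    expect_true(all(table(fix$participant_id, fix$picture_id) >= 6))
    got <- dyn2$mean_pct[dyn2$group == "patient" &
                           dyn2$subtype == "capture" & dyn2$k == k]
    expect_equal(got, recount("patient", "capture", k))
  }
})
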