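test_that("pose lengths are the incisal-cervical and cervical-apex distances", {
  a <- make_pose_ann(11L, c(3, 4), c(0, 0), c(100, 0))
  a$keypoints[a$keypoints$role == "cervical", c("x", "y")] <- c(100, 200)
  a$keypoints[a$keypoints$role == "apex", c("x", "y")] <- c(100, 340)
  a$keypoints[a$keypoints$role == "incisal", c("x", "y")] <- c(103, 204)
  len <- lengths_from_pose(a)
  expect_equal(len$root_length, 140)
  expect_equal(len$crown_length, 5)  # 3-4-5 triangle
})

test_that("pose lengths are invariant under rigid motions", {
  incisal <- c(1300, 730); cervical <- c(1290, 620); apex <- c(1310, 490)
  a <- make_pose_ann(21L, incisal, cervical, apex)
  base <- lengths_from_pose(a)
  center <- c(1450, 750)
  rot <- make_pose_ann(21L,
                       rotate_about(incisal, center, 30) + c(55, -12),
                       rotate_about(cervical, center, 30) + c(55, -12),
                       rotate_about(apex, center, 30) + c(55, -12))
  moved <- lengths_from_pose(rot)
  expect_lt(abs(moved$root_length - base$root_length), 1e-9)
  expect_lt(abs(moved$crown_length - base$crown_length), 1e-9)
})

test_that("missing keypoints and degenerate geometry are rejected", {
  a <- make_pose_ann(11L, c(0, 0), c(0, 100), c(0, 200),
                     visible = c(TRUE, FALSE, TRUE))
  expect_error(lengths_from_pose(a), "unmeasurable.*cervical")
  b <- make_pose_ann(11L, c(0, 0), c(0, 0), c(0, 200))
  expect_error(lengths_from_pose(b), "degenerate")
})

test_that("box lengths are the vertical box dimensions", {
  a <- make_detect_ann(11L,
                       c(x_center = 500, y_center = 700, width = 60,
                         height = 110),
                       c(x_center = 500, y_center = 500, width = 40,
                         height = 150))
  len <- lengths_from_boxes(a)
  expect_equal(len$root_length, 150)
  expect_equal(len$crown_length, 110)
  bad <- make_detect_ann(11L, a$crown_box,
                         c(x_center = 0, y_center = 0, width = 10,
                           height = 0))
  expect_error(lengths_from_boxes(bad), "degenerate box")
})

test_that("axis-aligned box height bounds the projected segment length", {
  L <- 130
  for (deg in c(0, 5, 10, 20)) {
    th <- deg * pi / 180
    p <- c(1000, 600)
    q <- p + L * c(sin(th), cos(th))
    tight <- box_from_segment(p, q, pad = 0)
    expect_equal(tight[["height"]], L * cos(th))
    padded <- box_from_segment(p, q, pad = 4)
    expect_gte(padded[["height"]], cos(th) * L)
  }
})

test_that("correction factor is the pre/post crown ratio with reciprocity", {
  expect_equal(correction_factor(110, 137.5), 0.8)
  expect_equal(correction_factor(73.2, 73.2), 1)
  set.seed(5)
  for (i in 1:100) {
    a <- runif(1, 50, 200); b <- runif(1, 50, 200)
    expect_equal(correction_factor(a, b) * correction_factor(b, a), 1)
  }
  expect_error(correction_factor(0, 10), "positive")
  expect_error(correction_factor(10, -1), "positive")
})

test_that("corrected final root cancels a uniform post-image magnification", {
  pre_crown <- 110; post_root_true <- 140
  for (m in c(0.5, 0.9, 1.1, 2.0)) {
    cf <- correction_factor(pre_crown, m * pre_crown)
    expect_equal(corrected_final_root(m * post_root_true, cf),
                 post_root_true, tolerance = 1e-12)
  }
  # worked example: post image magnified x1.25 so cf = 0.8
  expect_equal(corrected_final_root(175, 0.8), 140)
  expect_equal(corrected_final_root(93.5, 1), 93.5)
})

test_that("the printed-formula variant amplifies instead of cancelling", {
  cf <- correction_factor(110, 137.5)  # post magnified x1.25
  expect_equal(corrected_final_root(175, cf, formula = "printed"),
               175 / 0.8)
  expect_false(isTRUE(all.equal(
    corrected_final_root(175, cf, formula = "printed"), 140)))
})

test_that("resorption percent is the relative loss against the initial root", {
  expect_equal(resorption_percent(140, 140 * 2 / 3), 100 / 3)
  expect_equal(resorption_percent(140, 140), 0)
  expect_equal(resorption_percent(100, 110), -10)
  expect_lt(resorption_percent(100, 1e-9), 100)
  expect_error(resorption_percent(0, 50), "positive")
})

test_that("measure_patient recovers known resorption under magnification", {
  p <- make_manual_patient(true_resorption = c(0, 10, 25, 40),
                           magnification = 1.1)
  m <- measure_patient(p$pre, p$post, "pose")
  expect_true(all(m$measured))
  expect_lt(max(abs(m$resorption_percent - p$true_resorption)), 1e-6)
  expect_lt(max(abs(m$correction_factor - 1 / 1.1)), 1e-12)
})

test_that("identical pre and post annotations give exactly zero resorption", {
  p <- make_manual_patient(true_resorption = c(0, 0, 0, 0),
                           magnification = 1)
  m <- measure_patient(p$pre, p$pre, "pose")
  expect_equal(m$resorption_percent, rep(0, 4))
})

test_that("unmeasurable teeth are skipped with a reason, not fatal", {
  p <- make_manual_patient()
  p$pre[[2]]$keypoints$visible[3] <- FALSE
  m <- measure_patient(p$pre, p$post, "pose")
  expect_equal(sum(m$measured), 3)
  expect_match(m$skip_reason[m$tooth == 11], "unmeasurable")
  m2 <- measure_patient(p$pre[-1], p$post, "pose")
  expect_match(m2$skip_reason[m2$tooth == 12], "missing pre")
})

test_that("mixing annotation dialects raises a mode error", {
  p <- make_manual_patient()
  det <- list(make_detect_ann(12L,
                              c(x_center = 500, y_center = 700, width = 60,
                                height = 110),
                              c(x_center = 500, y_center = 500, width = 40,
                                height = 150)))
  expect_error(measure_patient(p$pre, det, "pose"), "mode")
})
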