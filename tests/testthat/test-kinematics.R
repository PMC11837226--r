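# keypoint cleaning, tail geometry, feature extraction, median smoothing

test_that("clean_keypoints drops low-confidence samples and interpolates", {
  kp <- kp_fixture(x = c(0, 5, 2), y = c(0, 5, 2), lik = c(1, 0.79, 1))
  out <- clean_keypoints(kp)
  expect_equal(out$data$nose_x[2], 1) # midpoint of (0,0) and (2,2)
  expect_equal(out$data$nose_y[2], 1)
  # confidence exactly at threshold is retained
  kp2 <- kp_fixture(x = c(0, 5, 2), lik = c(1, 0.8, 1))
  expect_equal(clean_keypoints(kp2)$data$nose_x[2], 5)
})

test_that("jump rule: > 15 px from previous retained sample is dropped", {
  # 16-px displacement dropped, 14-px retained
  kp <- kp_fixture(x = c(0, 16, 0), y = c(0, 0, 0))
  expect_equal(clean_keypoints(kp)$data$nose_x[2], 0)
  kp <- kp_fixture(x = c(0, 14, 0), y = c(0, 0, 0))
  expect_equal(clean_keypoints(kp)$data$nose_x[2], 14)
  # comparison is against the last *retained* sample: an outlier cannot
  # mask a later good point
  kp <- kp_fixture(x = c(0, 40, 3, 3), y = rep(0, 4))
  out <- clean_keypoints(kp)
  expect_equal(out$data$nose_x, c(0, 1.5, 3, 3))
})

test_that("clean_keypoints is a no-op on clean data and idempotent", {
  set.seed(1)
  x <- cumsum(rnorm(50, 0, 2))
  kp <- kp_fixture(x = x, y = x)
  once <- clean_keypoints(kp)
  expect_equal(once$data, kp$data)
  kpc <- kp_fixture(x = c(0, 100, 2, 3, 200, 5), y = rep(0, 6),
                    lik = c(1, 1, 1, 1, 0.5, 1))
  c1 <- clean_keypoints(kpc)
  c2 <- clean_keypoints(c1)
  expect_equal(c2$data, c1$data)
})

test_that("leading/trailing invalid samples take nearest valid value", {
  kp <- kp_fixture(x = c(9, 1, 2, 9), y = c(9, 1, 2, 9),
                   lik = c(0.1, 1, 1, 0.1))
  out <- clean_keypoints(kp)
  expect_equal(out$data$nose_x, c(1, 1, 2, 2))
})

test_that("a keypoint with no valid samples is a hard error naming it", {
  kp <- kp_fixture(x = 1:3, lik = rep(0.2, 3), bp = "tailtip")
  expect_error(clean_keypoints(kp), "tailtip")
})

test_that("tail_geometry recovers constructed bend angles", {
  straight <- bent_fish_contour(0)
  g <- tail_geometry(straight, head_kp = c(0, 0), tail_kp = c(160, 0))
  expect_lt(g$tail_angle, 1)       # colinear tail: angle ~ 0
  expect_lt(g$tail_deviation, 2)   # and no deviation from the body line
  for (ang in c(15, 30, 60)) {
    bent <- bent_fish_contour(ang)
    tail_tip <- bent[which.max(bent[, 1] * cos(ang * pi / 180) + bent[, 2] * sin(ang * pi / 180)), ]
    g <- tail_geometry(bent, head_kp = c(0, 0), tail_kp = tail_tip)
    expect_equal(g$tail_angle, ang, tolerance = 2)
  }
})

test_that("tail_geometry snaps to nearest contour vertex", {
  poly <- bent_fish_contour(0)
  v <- poly[7, ]
  g <- tail_geometry(poly, head_kp = v, tail_kp = poly[300, ])
  expect_equal(unname(g$contour_head), unname(v))
})

test_that("compute_features: hand kinematics oracle for speed", {
  # centroid displacement (3,4) px at px_per_cm = 10, 40 fps -> 20 cm/s
  n <- 5
  d <- data.frame(
    nose_x = (0:4) * 3 + 10, nose_y = (0:4) * 4, nose_likelihood = 1,
    left_operculum_x = (0:4) * 3 + 8, left_operculum_y = (0:4) * 4 + 2,
    left_operculum_likelihood = 1,
    right_operculum_x = (0:4) * 3 + 8, right_operculum_y = (0:4) * 4 - 2,
    right_operculum_likelihood = 1,
    centroid_x = (0:4) * 3, centroid_y = (0:4) * 4, centroid_likelihood = 1,
    tail_x = (0:4) * 3 - 10, tail_y = (0:4) * 4, tail_likelihood = 1)
  kp <- keypoint_table(d, frame_rate = 40, px_per_cm = 10)
  fs <- compute_features(kp, stimulus = stimulus_geometry("right", 500))
  expect_equal(fs$data$speed[-1], rep(20, n - 1))
  expect_equal(fs$data$speed[1], 0)
  # stationary frames -> zero speed
  d2 <- d; for (cc in grep("_x$|_y$", names(d2))) d2[[cc]] <- d2[[cc]][1]
  fs2 <- compute_features(keypoint_table(d2, frame_rate = 40, px_per_cm = 10),
                          stimulus = stimulus_geometry("right", 500))
  expect_true(all(fs2$data$speed == 0))
  # z channels flagged absent without a side view
  expect_true("elevation" %in% attr(fs, "absent_channels"))
  expect_null(fs$data$elevation)
})

test_that("orientation/operculum features are translation invariant", {
  tr <- cached_trial()
  kp <- render_keypoints(tr, 1, "top")
  kp2 <- kp
  for (bp in kp$bodyparts) {
    kp2$data[[paste0(bp, "_x")]] <- kp2$data[[paste0(bp, "_x")]] + 37
    kp2$data[[paste0(bp, "_y")]] <- kp2$data[[paste0(bp, "_y")]] - 11
  }
  stim <- rendered_stimulus_geometry()
  f1 <- compute_features(kp, stimulus = stim)
  f2 <- compute_features(kp2, stimulus = stim)
  for (ch in c("orientation", "speed", "turning_angle", "operculum_angle",
               "operculum_angle_left", "operculum_angle_right",
               "operculum_midline_dist"))
    expect_equal(f2$data[[ch]], f1$data[[ch]], tolerance = 1e-9)
  expect_equal(f2$data$centroid_x, f1$data$centroid_x + 37 / kp$px_per_cm)
})

test_that("median_smooth matches a direct sliding-median oracle", {
  expect_error(median_smooth(1:10, window_frames = 4), "odd")
  set.seed(3)
  x <- rnorm(60)
  sm <- median_smooth(x, 11)
  oracle <- sapply(seq_along(x), function(i)
    median(x[max(1, i - 5):min(60, i + 5)]))
  expect_equal(sm, oracle)
  # constant channel unchanged; isolated spike removed
  expect_equal(median_smooth(rep(2, 30), 11), rep(2, 30))
  spike <- rep(0, 30); spike[15] <- 1
  expect_equal(median_smooth(spike, 11), rep(0, 30))
  # window metadata: 11 frames at 40 fps spans 0.275 s
  fs <- feature_series(data.frame(a = rnorm(50)), frame_rate = 40)
  expect_equal(attr(median_smooth(fs, 11), "window_s"), 0.275)
})

test_that("contour CSV round trip feeds tail channels", {
  contours <- list(bent_fish_contour(20), NULL, bent_fish_contour(40))
  p <- file.path(tempdir(), "contours.csv")
  write_contours_csv(contours, p)
  back <- read_contours_csv(p, n_frames = 3)
  expect_null(back[[2]])
  expect_equal(back[[1]], unname(contours[[1]]))
  g <- tail_geometry(back[[3]], head_kp = c(0, 0), tail_kp = c(146, 39))
  expect_equal(g$tail_angle, 40, tolerance = 2)
})

test_that("keypoint and feature CSV round trips", {
  tr <- cached_trial()
  kp <- render_keypoints(tr, 1, "top")
  kp$data <- kp$data[1:50, ]
  p <- file.path(tempdir(), "kp.csv")
  write_keypoints_csv(kp, p)
  back <- read_keypoints_csv(p)
  expect_equal(back$data, kp$data, tolerance = 1e-8)
  expect_equal(back$frame_rate, kp$frame_rate)
  # multi-row pose-tracker header dialect
  p2 <- file.path(tempdir(), "kp_dlc.csv")
  hdr <- c("scorer,model,model,model",
           "bodyparts,nose,nose,nose",
           "coords,x,y,likelihood")
  rows <- sprintf("%d,%.3f,%.3f,1.0", 0:9, 1:10, 11:20)
  writeLines(c(hdr, rows), p2)
  d <- read_keypoints_csv(p2, px_per_cm = 10)
  expect_equal(d$data$nose_x, as.numeric(1:10))
  expect_equal(d$bodyparts, "nose")
  stim <- rendered_stimulus_geometry()
  fs <- compute_features(kp, stimulus = stim)
  pf <- file.path(tempdir(), "feat.csv")
  write_features_csv(fs, pf)
  fback <- read_features_csv(pf)
  expect_equal(fback$data, fs$data, tolerance = 1e-6)
  expect_equal(fback$frame_rate, fs$frame_rate)
})
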