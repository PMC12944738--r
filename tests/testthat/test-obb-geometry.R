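test_that("YOLO-OBB label parsing de-normalises corners and rejects malformed lines", {
  dir <- withr::local_tempdir()
  writeLines("0 0.1 0.1 0.2 0.1 0.2 0.15 0.1 0.15",
             file.path(dir, "frame_000000.txt"))
  det <- read_obb_detections(dir, "yolo_obb_txt",
                             image_width = 1000, image_height = 1000)
  expect_equal(nrow(det), 1L)
  expect_equal(unlist(det[1, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")],
                      use.names = FALSE),
               c(100, 100, 200, 100, 200, 150, 100, 150))
  expect_equal(det$class, "bar")

  empty <- withr::local_tempdir()
  expect_equal(nrow(read_obb_detections(empty, "yolo_obb_txt")), 0L)

  writeLines("0 0.1 0.1 0.2 0.1 0.2 0.15 0.1", # 7 coordinates
             file.path(dir, "frame_000001.txt"))
  expect_error(read_obb_detections(dir, "yolo_obb_txt"), class = "lp_parse_error")
})

test_that("long-CSV dialect round-trips through the YOLO writer", {
  sim <- simulate_press(press_config(seed = 11, corner_noise_sigma = 1))
  dir <- withr::local_tempdir()
  write_obb_labels(sim$detections, dir)
  back <- read_obb_detections(dir, "yolo_obb_txt")
  expect_equal(nrow(back), nrow(sim$detections))
  expect_equal(back$x1, sim$detections$x1, tolerance = 1e-4)
  expect_equal(back$y3, sim$detections$y3, tolerance = 1e-4)

  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sim$detections, csv)
  det2 <- read_obb_detections(csv, "long_csv")
  expect_equal(det2$x2, sim$detections$x2)
})

test_that("axis midpoints follow the longer-side rule including the tie branch", {
  # 10x2 rectangle: first listed side is the long one
  d <- axis_midpoints(det_from_corners(rbind(c(0, 0), c(10, 0), c(10, 2), c(0, 2))))
  expect_equal(c(d$L1, d$L2), c(10, 2))
  expect_equal(c(d$m1x, d$m1y, d$m2x, d$m2y), c(0, 1, 10, 1))
  # 2x10: else-branch
  d <- axis_midpoints(det_from_corners(rbind(c(0, 0), c(2, 0), c(2, 10), c(0, 10))))
  expect_equal(c(d$m1x, d$m1y, d$m2x, d$m2y), c(1, 0, 1, 10))
  # square tie goes to the else-branch
  d <- axis_midpoints(det_from_corners(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))))
  expect_equal(c(d$L1, d$L2), c(4, 4))
  expect_equal(c(d$m1x, d$m1y, d$m2x, d$m2y), c(2, 0, 2, 4))
})

test_that("midpoint separation equals the longer side for random rectangles", {
  set.seed(101)
  for (i in 1:50) {
    long <- runif(1, 5, 50)
    d <- axis_midpoints(random_rectangle(long = long))
    expect_equal(sqrt((d$m1x - d$m2x)^2 + (d$m1y - d$m2y)^2), long,
                 tolerance = 1e-9)
  }
})

test_that("end classification picks the higher (smaller image-y) endpoint, tie to M2", {
  mk <- function(m1, m2) {
    tibble::tibble(m1x = m1[1], m1y = m1[2], m2x = m2[1], m2y = m2[2])
  }
  r <- classify_ends(mk(c(512, 120), c(300, 600)))
  expect_equal(c(r$moving_x, r$moving_y), c(512, 120))
  r <- classify_ends(mk(c(0, 400), c(900, 50)))
  expect_equal(c(r$moving_x, r$moving_y), c(900, 50))
  r <- classify_ends(mk(c(10, 77), c(20, 77))) # exact tie
  expect_equal(c(r$moving_x, r$moving_y), c(20, 77))
})

test_that("classification of a box is invariant to cyclic corner rotation", {
  set.seed(202)
  for (i in 1:20) {
    corners <- random_rectangle()
    m <- matrix(unlist(corners[1, c("x1", "y1", "x2", "y2", "x3", "y3",
                                    "x4", "y4")]), ncol = 2, byrow = TRUE)
    base <- classify_ends(axis_midpoints(det_from_corners(m)))
    for (shift in 1:3) {
      rot <- m[c((shift:(shift + 3)) %% 4 + 1), , drop = FALSE]
      r <- classify_ends(axis_midpoints(det_from_corners(rot)))
      expect_equal(c(r$moving_x, r$moving_y, r$fixed_x, r$fixed_y),
                   c(base$moving_x, base$moving_y, base$fixed_x, base$fixed_y),
                   tolerance = 1e-9)
    }
  }
})

test_that("track building interpolates short gaps and splits on long ones", {
  sim <- simulate_press(press_config(seed = 4))
  det <- sim$detections
  full <- build_end_track(det, fps = 50)
  expect_false(any(full$interpolated))
  expect_equal(unique(full$block), 1L)

  # knock out one interior frame: linear interpolation, flagged
  det1 <- det[det$frame != 40L, ]
  tr <- build_end_track(det1, fps = 50, max_gap = 2)
  row <- tr[tr$frame == 40L, ]
  expect_true(row$interpolated)
  nb <- tr[tr$frame %in% c(39L, 41L), ]
  expect_equal(row$moving_x, mean(nb$moving_x), tolerance = 1e-9)
  expect_equal(row$moving_y, mean(nb$moving_y), tolerance = 1e-9)

  # a gap longer than max_gap splits the track into blocks
  det2 <- det[det$frame < 30L | det$frame > 60L, ]
  tr2 <- build_end_track(det2, fps = 50, max_gap = 5)
  expect_equal(sort(unique(tr2$block)), c(1L, 2L))

  # two isolated frames -> two single-frame blocks -> insufficient data
  det3 <- det[det$frame %in% c(0L, 10L), ]
  expect_error(build_end_track(det3, fps = 50, max_gap = 3),
               class = "lp_insufficient_data")
})

test_that("marker-class frames use box centres and distrust inconsistent labels", {
  sim <- simulate_press(press_config(seed = 9, classes = "markers"))
  tr <- build_end_track(sim$detections, fps = 50)
  expect_equal(nrow(tr), nrow(sim$truth))
  # swap the labels on one frame: geometry wins with a warning
  det <- sim$detections
  i_mv <- which(det$frame == 10L & det$class == "moving_marker")
  i_fx <- which(det$frame == 10L & det$class == "fixed_marker")
  det$class[c(i_mv, i_fx)] <- c("fixed_marker", "moving_marker")
  expect_warning(tr2 <- build_end_track(det, fps = 50),
                 class = "lp_class_disagreement")
  expect_equal(tr2$moving_y[tr2$frame == 10L], tr$moving_y[tr$frame == 10L])
})

test_that("calibration recovers the scale factor and fixes the mean bar length", {
  sim <- simulate_press(press_config(seed = 5))
  track <- build_end_track(sim$detections, fps = 50)
  traj <- calibrate(track, bar_length = 2.20)
  expect_equal(attr(traj, "scale_s"), sim$true_scale, tolerance = 1e-6)
  # identity forced by the scale definition: mean metre bar length = L_real
  len_m <- sqrt((traj$x - traj$fixed_x)^2 + (traj$y - traj$fixed_y)^2)
  expect_equal(mean(len_m), 2.20, tolerance = 1e-12)
  expect_gt(attr(traj, "scale_s"), 0)
  # scale and L_pixel are consistent to numerical precision
  expect_equal(attr(traj, "scale_s") * attr(traj, "L_pixel_mean"), 2.20,
               tolerance = 1e-9)
})

test_that("constant pixel bar length gives s = L_real / L_pixel exactly", {
  frames <- 0:9
  det <- purrr::map(frames, function(f) {
    det_from_corners(rbind(c(500, 900), c(500 + 1100, 900),
                           c(500 + 1100, 910), c(500, 910)), frame = f)
  }) |> purrr::list_rbind()
  # horizontal bar: give it a slight tilt so moving/fixed are distinct rows
  det$y2 <- det$y2 - 300; det$y3 <- det$y3 - 300
  track <- build_end_track(det, fps = 50)
  d_px <- mean(sqrt((track$moving_x - track$fixed_x)^2 +
                      (track$moving_y - track$fixed_y)^2))
  traj <- calibrate(track, bar_length = 2.20)
  expect_equal(attr(traj, "scale_s"), 2.20 / d_px, tolerance = 1e-12)
})

test_that("trajectory recovery is near-exact noiseless and degrades monotonically with noise", {
  errs <- purrr::map_dbl(c(0, 1, 2, 4), function(sigma) {
    err <- purrr::map_dbl(1:3, function(r) {
      sim <- simulate_press(press_config(corner_noise_sigma = sigma,
                                         seed = 100 + 10 * r + sigma))
      track <- build_end_track(sim$detections, fps = 50)
      traj <- calibrate(track, bar_length = 2.20)
      x_true <- 2.20 * cos(sim$truth$theta)
      y_true <- 2.20 * sin(sim$truth$theta)
      mean(sqrt((traj$x - x_true)^2 + (traj$y - y_true)^2))
    })
    mean(err)
  })
  expect_lt(errs[1], 1e-6)
  expect_true(all(diff(errs) > 0))
})
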