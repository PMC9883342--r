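# Crop geometry, Gaussian encoding/decoding and the masked MSE.

test_that("crop window scales area by the configured factor around the box center", {
  img <- array(0.5, c(100, 100, 3))
  cr <- make_crop(img, c(10, 10, 50, 50), 2.2, c(64L, 64L))
  cb <- cr$geom$crop_box
  side <- cb[3] - cb[1]
  expect_equal(side, 40 * sqrt(2.2), tolerance = 1e-9)
  expect_equal(side, 59.33, tolerance = 1e-2)
  expect_equal((cb[3] - cb[1]) * (cb[4] - cb[2]) / (40 * 40), 2.2, tolerance = 1e-12)
  expect_equal((cb[1] + cb[3]) / 2, 30)
  expect_equal((cb[2] + cb[4]) / 2, 30)

  cr1 <- make_crop(img, c(10, 10, 50, 50), 1.0, c(64L, 64L))
  expect_equal(cr1$geom$crop_box, c(10, 10, 50, 50))

  expect_error(make_crop(img, c(200, 200, 240, 240)), class = "ht_geometry_error")
})

test_that("frame->crop->frame is the identity within 1e-6 px", {
  img <- array(0, c(80, 120, 3))
  cr <- make_crop(img, c(20, 10, 60, 70), 2.2, c(128L, 96L))
  pts <- cbind(runif(50, 0, 119), runif(50, 0, 79))
  back <- crop_to_frame(cr$geom, frame_to_crop(cr$geom, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("encoding peaks at 1.0 on the joint cell and masks the right joints", {
  img <- array(0, c(100, 100, 3))
  box <- c(20, 20, 60, 60)
  cr <- make_crop(img, box, 2.2, c(64L, 64L))
  xy <- grid_pose_xy(25, 25, 30, 30)
  xy[1, ] <- c(40, 40)                      # wrist at crop center
  state <- rep("visible", 21)
  state[5] <- "unannotated"
  xy[9, ] <- c(cr$geom$crop_box[3] + 10, 40)  # 10 px outside the crop window
  pose <- hand_pose(xy, state, "right", box)
  hm <- encode_heatmaps(pose, cr$geom, 2, c(64L, 64L))

  ch <- hm$values[1, , ]
  expect_equal(max(ch), 1.0)
  # crop center maps to grid coordinate 31.5 -> cell 32 (0-based), i.e. [33, 33]
  expect_equal(which(ch == 1, arr.ind = TRUE)[1, ], c(row = 33, col = 33),
               ignore_attr = TRUE)
  expect_false(hm$mask[5])
  expect_equal(sum(hm$values[5, , ]), 0)
  expect_false(hm$mask[9])
  expect_equal(sum(hm$values[9, , ]), 0)
  expect_true(all(hm$mask[-c(5, 9)]))

  expect_error(encode_heatmaps(pose, cr$geom, -1), class = "ht_schema_error")
})

test_that("decoding inverts a one-hot channel and ties break to cell (0,0)", {
  img <- array(0, c(100, 100, 3))
  cr <- make_crop(img, c(20, 20, 60, 60), 2.2, c(64L, 64L))
  vals <- array(0, c(21, 64, 64))
  vals[1, 11, 21] <- 1   # row 10, col 20 zero-based
  stack <- heatmap_stack(vals)
  dec <- decode_heatmaps(stack, cr$geom)
  expect_equal(dec$confidence[1], 1.0)
  expected <- handtrack:::grid_to_frame(cr$geom, cbind(20, 10), c(64, 64))
  expect_equal(dec$xy[1, ], as.numeric(expected), tolerance = 1e-9)
  # all-zero channel: confidence 0, location = cell (0,0) mapped
  expect_equal(dec$confidence[2], 0)
  corner <- handtrack:::grid_to_frame(cr$geom, cbind(0, 0), c(64, 64))
  expect_equal(dec$xy[2, ], as.numeric(corner), tolerance = 1e-9)
})

test_that("decode(encode(pose)) recovers interior joints to half a grid cell", {
  img <- array(0, c(120, 120, 3))
  set.seed(42)
  worst <- 0
  for (i in 1:50) {
    box <- c(runif(1, 5, 30), runif(1, 5, 30), runif(1, 60, 110), runif(1, 60, 110))
    cr <- make_crop(img, box, 2.2, c(64L, 64L))
    cb <- cr$geom$crop_box
    mx <- 0.15 * (cb[3] - cb[1]); my <- 0.15 * (cb[4] - cb[2])
    xy <- cbind(runif(21, cb[1] + mx, cb[3] - mx), runif(21, cb[2] + my, cb[4] - my))
    pose <- hand_pose(xy, rep("visible", 21), "right", box)
    hm <- encode_heatmaps(pose, cr$geom, 2, c(64L, 64L))
    dec <- decode_heatmaps(hm, cr$geom)
    cw <- (cb[3] - cb[1]) / 64; chh <- (cb[4] - cb[2]) / 64
    err <- pmax(abs(dec$xy[, 1] - xy[, 1]) / cw, abs(dec$xy[, 2] - xy[, 2]) / chh)
    worst <- max(worst, max(err))
  }
  expect_lte(worst, 0.5 + 1e-9)
})

test_that("encoding is equivariant to joint translation of pose and box", {
  img <- array(0, c(200, 200, 3))
  box <- c(20, 20, 60, 60)
  pose <- make_pose(20, 20, 40, 40)
  cr <- make_crop(img, box, 2.2, c(64L, 64L))
  hm <- encode_heatmaps(pose, cr$geom, 2, c(32L, 32L))
  sh <- shift_pose(pose, 53, 31)
  cr2 <- make_crop(img, sh$box, 2.2, c(64L, 64L))
  hm2 <- encode_heatmaps(sh, cr2$geom, 2, c(32L, 32L))
  expect_equal(hm2$values, hm$values, tolerance = 1e-9)
  expect_identical(hm2$mask, hm$mask)
})

test_that("masked MSE matches hand arithmetic and its zero conditions", {
  g <- heatmap_stack(array(0, c(1, 2, 2)))
  p <- heatmap_stack(array(c(1, 0, 0, 0), c(1, 2, 2)))
  expect_equal(masked_mse(p, g), 0.25)
  expect_equal(masked_mse(g, g), 0)
  pm <- p; pm$mask <- FALSE
  expect_equal(masked_mse(pm, g), 0)

  set.seed(1)
  a <- heatmap_stack(array(runif(21 * 8 * 8), c(21, 8, 8)))
  b <- heatmap_stack(array(runif(21 * 8 * 8), c(21, 8, 8)))
  expect_gt(masked_mse(a, b), 0)
  expect_equal(masked_mse(a, a), 0)
  expect_error(masked_mse(a, g), class = "ht_schema_error")
})
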