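# Domain types, validation, and the clip JSON dialect.

test_that("save/load round-trips clips structurally and byte-stably", {
  clip <- generate_clip(synth_config(n_frames = 4L, n_hands = 2L, seed = 7L))$annotation
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_clip(clip, p1)
  c1 <- load_clip(p1)
  save_clip(c1, p2)
  expect_identical(readBin(p1, "raw", 1e7), readBin(p2, "raw", 1e7))
  expect_equal(load_clip(p2), c1)
})

test_that("round-trip identity holds over randomly generated clips", {
  for (seed in 1:5) {
    clip <- generate_clip(synth_config(n_frames = 3L, seed = seed))$annotation
    p <- withr::local_tempfile(fileext = ".json")
    save_clip(clip, p)
    back <- load_clip(p)
    expect_equal(back$clip_id, clip$clip_id)
    expect_equal(length(back$frames), length(clip$frames))
    for (k in seq_along(clip$frames)) {
      fa <- clip$frames[[k]]; fb <- back$frames[[k]]
      expect_equal(fb$frame_index, fa$frame_index)
      expect_equal(length(fb$hands), length(fa$hands))
      for (h in seq_along(fa$hands)) {
        expect_equal(fb$hands[[h]]$xy, fa$hands[[h]]$xy, tolerance = 1e-12)
        expect_identical(fb$hands[[h]]$state, fa$hands[[h]]$state)
        expect_identical(fb$hands[[h]]$track_id, fa$hands[[h]]$track_id)
      }
    }
  }
})

test_that("schema violations are rejected with the offending field named", {
  clip <- make_clip(list(list(make_pose(track_id = 0L))))
  p <- withr::local_tempfile(fileext = ".json")
  save_clip(clip, p)

  raw <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  raw$frames[[1]]$hands[[1]]$keypoints <- raw$frames[[1]]$hands[[1]]$keypoints[1:20]
  p20 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(raw, auto_unbox = TRUE, null = "null", digits = NA), p20)
  expect_error(load_clip(p20), "keypoints.*20", class = "ht_schema_error")

  expect_error(
    make_clip(list(list(make_pose(track_id = 1L), make_pose(50, 50, track_id = 1L)))),
    "track_id", class = "ht_schema_error")

  expect_error(hand_pose(grid_pose_xy(), rep("visible", 21), "right",
                         c(10, 10, 5, 20)),
               "x1 > x0", class = "ht_schema_error")
  expect_error(hand_pose(grid_pose_xy(), rep("maybe", 21), "right",
                         c(0, 0, 10, 10)),
               "state", class = "ht_schema_error")
})

test_that("fuzzing valid clips with single mutations is caught, valid input is not", {
  clip <- generate_clip(synth_config(n_frames = 2L, n_hands = 2L, seed = 3L))$annotation
  expect_silent(handtrack:::validate_clip(clip))
  bad1 <- clip
  bad1$frames[[2]]$frame_index <- bad1$frames[[1]]$frame_index
  expect_error(handtrack:::validate_clip(bad1), "increasing", class = "ht_schema_error")
  bad2 <- clip
  bad2$frames[[1]]$hands[[1]]$handedness <- "ambidextrous"
  expect_error(handtrack:::validate_clip(bad2), "handedness", class = "ht_schema_error")
  bad3 <- clip
  bad3$frames[[1]]$hands[[1]]$confidence <- rep(2, 21)
  expect_error(handtrack:::validate_clip(bad3), "confidence", class = "ht_schema_error")
})

test_that("empty clips and unset track ids survive the dialect", {
  empty <- clip_annotation("empty", 8, list())
  p <- withr::local_tempfile(fileext = ".json")
  save_clip(empty, p)
  back <- load_clip(p)
  expect_length(back$frames, 0)

  untracked <- make_clip(list(list(make_pose())))
  save_clip(untracked, p)
  expect_match(paste(readLines(p), collapse = ""), "\"track_id\":null")
  expect_null(load_clip(p)$frames[[1]]$hands[[1]]$track_id)
})

test_that("unknown fields are preserved on round-trip", {
  clip <- make_clip(list(list(make_pose(track_id = 0L))))
  clip$extra <- list(annotator = jsonlite::unbox("amt-17"))
  p <- withr::local_tempfile(fileext = ".json")
  save_clip(clip, p)
  back <- load_clip(p)
  expect_equal(as.character(back$extra$annotator), "amt-17")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_clip(back, p2)
  expect_match(paste(readLines(p2), collapse = ""), "amt-17")
})

test_that("detection files group boxes by frame and reject bad rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  save_detections(data.frame(frame_index = c(0L, 2L, 2L),
                             x0 = c(0, 10, 50), y0 = c(0, 10, 5),
                             x1 = c(20, 30, 80), y1 = c(20, 40, 45),
                             score = c(0.9, 0.8, 0.7)), p)
  det <- load_detections(p)
  expect_length(det$for_frame(0L), 1)
  expect_length(det$for_frame(1L), 0)
  expect_length(det$for_frame(2L), 2)
  expect_equal(det$for_frame(2L)[[1]]$score, 0.8)

  bad <- withr::local_tempfile(fileext = ".csv")
  save_detections(data.frame(frame_index = 0L, x0 = 30, y0 = 0, x1 = 20, y1 = 10), bad)
  expect_error(load_detections(bad), class = "ht_schema_error")
})
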