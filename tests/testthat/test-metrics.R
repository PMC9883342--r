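# PCK, pose matching, average precision and the tracking scores.

test_that("PCK thresholds at sigma times the box side and is scale invariant", {
  ev <- eval_config()
  gt <- make_pose(10, 10, 40, 40)
  expect_equal(pck_match(gt, gt, ev)$pck, 1.0)

  pred <- gt
  pred$xy[1, ] <- gt$xy[1, ] + c(0.21 * 40, 0)   # just past sigma * max side
  res <- pck_match(pred, gt, ev)
  expect_false(res$correct[1])
  expect_equal(res$pck, 20 / 21)
  pred$xy[1, ] <- gt$xy[1, ] + c(0.19 * 40, 0)
  expect_true(pck_match(pred, gt, ev)$correct[1])

  # uniform 3x scaling of pose and box leaves PCK unchanged
  scale3 <- function(p) {
    p$xy <- p$xy * 3; p$box <- p$box * 3; p
  }
  pred2 <- gt
  set.seed(11)
  pred2$xy <- pred2$xy + matrix(rnorm(42, 0, 5), 21, 2)
  expect_equal(pck_match(scale3(pred2), scale3(gt), ev)$pck,
               pck_match(pred2, gt, ev)$pck)

  # occluded joints are annotated: they count toward the denominator
  gto <- gt; gto$state[3] <- "occluded"
  expect_equal(pck_match(gt, gto, ev)$pck, 1.0)
  gtu <- gt; gtu$state[3] <- "unannotated"
  expect_true(is.na(pck_match(gt, gtu, ev)$correct[3]))
})

test_that("pose assignment is greedy by PCK and leaves leftovers unmatched", {
  ev <- eval_config()
  gt <- make_pose(10, 10, 40, 40)
  near <- gt
  far <- gt
  far$xy[1:5, ] <- far$xy[1:5, ] + 20      # 5 joints pushed past the gate
  am <- assign_poses(list(far, near), list(gt), ev)
  expect_equal(nrow(am$pairs), 1)
  expect_equal(unname(am$pairs[1, "pred"]), 2)   # higher-PCK prediction wins
  expect_equal(am$unmatched_preds, 1)
  expect_length(assign_poses(list(), list(gt), ev)$unmatched_gts, 1)
  # zero-PCK pairs are never matched
  outside <- shift_pose(gt, 500, 500)
  am2 <- assign_poses(list(outside), list(gt), ev)
  expect_equal(nrow(am2$pairs), 0)
})

test_that("mAP is 100 for perfect predictions, 0 for none, and matches a
           brute-force PR oracle on a 2-candidate ranking", {
  gt <- make_clip(list(list(make_pose(track_id = 0L)),
                       list(make_pose(12, 10, track_id = 0L))))
  perfect <- make_clip(list(list(with_conf(make_pose(track_id = 0L))),
                            list(with_conf(make_pose(12, 10, track_id = 0L)))))
  expect_equal(evaluate_map(perfect, gt)$map, 100)

  none <- make_clip(list(list(), list()))
  expect_equal(evaluate_map(none, gt)$map, 0)

  # joint 1: correct detection at conf 0.9 plus spurious pose at conf 0.8
  gt1 <- make_clip(list(list(make_pose(track_id = 0L))))
  spurious <- shift_pose(make_pose(track_id = 1L), 300, 300)
  preds <- make_clip(list(list(with_conf(make_pose(track_id = 0L), rep(0.9, 21)),
                               with_conf(spurious, rep(0.8, 21)))))
  res <- evaluate_map(preds, gt1)
  # brute-force PR: ranked (TP, FP) -> precision 1 at recall 1, then 1/2;
  # interpolated area = 1
  ranked <- c(TRUE, FALSE)
  tp <- cumsum(ranked); fp <- cumsum(!ranked)
  rec <- tp / 1; prec <- tp / (tp + fp)
  ap_oracle <- 0
  for (r in unique(rec[ranked])) ap_oracle <- ap_oracle +
    (r - max(0, rec[which(rec == r)[1] - 1])) * max(prec[rec >= r])
  expect_equal(res$ap[1], 100 * ap_oracle)
  expect_equal(res$ap[1], 100)
})

test_that("mAP is invariant to clip order and AP drops when correct keypoints
           are demoted below spurious ones", {
  gt1 <- make_clip(list(list(make_pose(track_id = 0L))), "a")
  gt2 <- make_clip(list(list(make_pose(30, 30, track_id = 0L))), "b")
  p1 <- make_clip(list(list(with_conf(make_pose(track_id = 0L), rep(0.9, 21)))), "a")
  p2 <- make_clip(list(list(with_conf(shift_pose(make_pose(30, 30, track_id = 0L), 2, 0),
                                      rep(0.6, 21)))), "b")
  r12 <- evaluate_map(list(p1, p2), list(gt1, gt2))
  r21 <- evaluate_map(list(p2, p1), list(gt2, gt1))
  expect_equal(r12$map, r21$map)

  # demotion: correct keypoint below a spurious one lowers (or keeps) AP
  gt <- make_clip(list(list(make_pose(track_id = 0L))))
  spur <- shift_pose(make_pose(track_id = 1L), 300, 300)
  hi <- make_clip(list(list(with_conf(make_pose(track_id = 0L), rep(0.9, 21)),
                            with_conf(spur, rep(0.5, 21)))))
  lo <- make_clip(list(list(with_conf(make_pose(track_id = 0L), rep(0.4, 21)),
                            with_conf(spur, rep(0.5, 21)))))
  expect_lte(evaluate_map(lo, gt)$ap[1], evaluate_map(hi, gt)$ap[1])
})

test_that("MOTA closed forms: perfect 100, absent predictions 0, one id switch 50", {
  gt <- make_clip(list(list(make_pose(track_id = 0L)),
                       list(make_pose(12, 10, track_id = 0L))))
  perfect <- make_clip(list(list(with_conf(make_pose(track_id = 5L))),
                            list(with_conf(make_pose(12, 10, track_id = 5L)))))
  res <- evaluate_mota(perfect, gt)
  expect_equal(res$report$mota, 100)
  expect_equal(res$report$motp, 100)
  expect_equal(res$report$precision, 100)
  expect_equal(res$report$recall, 100)
  expect_equal(res$report$f1, 100)

  none <- make_clip(list(list(), list()))
  res0 <- evaluate_mota(none, gt)
  expect_equal(res0$report$mota, 0)
  expect_equal(sum(res0$counts$FN), sum(res0$counts$G))

  switch <- make_clip(list(list(with_conf(make_pose(track_id = 1L))),
                           list(with_conf(make_pose(12, 10, track_id = 2L)))))
  ressw <- evaluate_mota(switch, gt)
  expect_equal(sum(ressw$counts$IDSW), sum(ressw$counts$G) / 2)
  expect_equal(ressw$report$mota, 50)
})

test_that("MOTA is 100 only without errors, decreases with any FP, and can go
           below zero", {
  gt <- make_clip(list(list(make_pose(track_id = 0L))))
  good <- make_clip(list(list(with_conf(make_pose(track_id = 0L)))))
  expect_equal(evaluate_mota(good, gt)$report$mota, 100)
  extra <- make_clip(list(list(with_conf(make_pose(track_id = 0L)),
                               with_conf(shift_pose(make_pose(track_id = 3L), 300, 300)))))
  expect_lt(evaluate_mota(extra, gt)$report$mota, 100)
  # many spurious poses: MOTA < 0, never > 100
  flood <- make_clip(list(list(with_conf(make_pose(track_id = 0L)),
                               with_conf(shift_pose(make_pose(track_id = 3L), 300, 300)),
                               with_conf(shift_pose(make_pose(track_id = 4L), 600, 0)),
                               with_conf(shift_pose(make_pose(track_id = 5L), 0, 600)))))
  expect_lt(evaluate_mota(flood, gt)$report$mota, 0)
})

test_that("the package MOTA agrees exactly with the brute-force oracle on the
           closed-form fixtures", {
  gt <- make_clip(list(list(make_pose(track_id = 0L)),
                       list(make_pose(12, 10, track_id = 0L))))
  switch <- make_clip(list(list(with_conf(make_pose(track_id = 1L))),
                           list(with_conf(make_pose(12, 10, track_id = 2L)))))
  ours <- evaluate_mota(switch, gt)
  oracle <- oracle_track_counts(switch, gt)
  expect_equal(sum(ours$counts$FN), oracle$FN)
  expect_equal(sum(ours$counts$FP), oracle$FP)
  expect_equal(sum(ours$counts$IDSW), oracle$IDSW)
  expect_equal(ours$report$mota, oracle$mota)
})
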