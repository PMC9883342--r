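# Similarity functions, assignment, and track lifecycle.

test_that("IoU matches hand arithmetic and is symmetric", {
  a <- c(0, 0, 2, 2)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, c(5, 5, 7, 7)), 0)
  b <- c(1, 0, 3, 2)
  expect_equal(iou(a, b), 1 / 3)
  set.seed(4)
  for (i in 1:20) {
    p <- c(sort(runif(2, 0, 50)), sort(runif(2, 0, 50)))[c(1, 3, 2, 4)]
    q <- c(sort(runif(2, 0, 50)), sort(runif(2, 0, 50)))[c(1, 3, 2, 4)]
    expect_equal(iou(p, q), iou(q, p))
    expect_true(iou(p, q) >= 0 && iou(p, q) <= 1)
  }
})

test_that("mean keypoint distance averages over jointly annotated joints", {
  a <- make_pose()
  expect_equal(mean_keypoint_distance(a, a), 0)
  b <- shift_pose(a, 3, 4)
  expect_equal(mean_keypoint_distance(a, b), 5)

  a2 <- a; a2$state <- c(rep("visible", 10), rep("unannotated", 11))
  b2 <- b; b2$state <- c(rep("unannotated", 5), rep("visible", 10),
                         rep("unannotated", 6))
  # brute-force reference over the shared joints 6..10
  ref <- mean(sapply(6:10, function(j) sqrt(sum((a2$xy[j, ] - b2$xy[j, ])^2))))
  expect_equal(mean_keypoint_distance(a2, b2), ref)
  c2 <- a; c2$state <- rep("unannotated", 21)
  expect_true(is.na(mean_keypoint_distance(a, c2)))
})

test_that("greedy assignment is injective and optimal on diagonal-dominant costs", {
  set.seed(9)
  for (trial in 1:30) {
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    S <- matrix(runif(n * m), n, m)
    k <- min(n, m)
    for (i in seq_len(k)) S[i, i] <- 2 + runif(1)   # diagonal dominance
    g <- greedy_assign(S)
    expect_true(all(!duplicated(stats::na.omit(g))))
    o <- ht_ns$optimal_assign(S)
    expect_identical(g[seq_len(k)], o[seq_len(k)])
  }
  expect_equal(greedy_assign(matrix(0.7, 1, 1)), 1L)
  expect_identical(ht_ns$optimal_assign(matrix(0.7, 1, 1)), 1L)
})

test_that("greedy equals exhaustive optimum on 1x1 and identity-like cases", {
  S <- matrix(c(0.9, -Inf, -Inf, 0.8), 2, 2)
  expect_equal(greedy_assign(S), c(1L, 2L))
  expect_equal(ht_ns$optimal_assign(S), c(1L, 2L))
  expect_equal(greedy_assign(matrix(-Inf, 2, 2)), c(NA_integer_, NA_integer_))
})

test_that("cold start assigns fresh ids 0..k-1 and static scenes keep ids", {
  trk <- new_tracker("iou")
  dets <- lapply(0:2, function(i) list(pose = make_pose(10 + 60 * i, 10)))
  st <- step_tracker(trk, dets)
  expect_equal(st$assignments, 0:2)
  for (rep in 1:4) {
    st <- step_tracker(st$state, dets)
    expect_equal(st$assignments, 0:2)
  }
  # per-frame assignment stays injective with jitter
  set.seed(2)
  state <- new_tracker("l2")
  for (t in 1:6) {
    dd <- lapply(0:2, function(i)
      list(pose = shift_pose(make_pose(10 + 60 * i, 10), rnorm(1), rnorm(1))))
    st <- step_tracker(state, dd)
    state <- st$state
    expect_false(any(duplicated(st$assignments)))
  }
})

test_that("unmatched tracks expire after max_age frames", {
  trk <- new_tracker("iou", max_age = 2L)
  st <- step_tracker(trk, list(list(pose = make_pose(10, 10))))
  expect_equal(st$assignments, 0L)
  st <- step_tracker(st$state, list())        # age 1, still alive
  expect_length(st$state$tracks, 1)
  st <- step_tracker(st$state, list(list(pose = make_pose(12, 10))))
  expect_equal(st$assignments, 0L)            # re-matched after the gap
  st <- step_tracker(st$state, list())
  st <- step_tracker(st$state, list())        # age reaches max_age -> expired
  expect_length(st$state$tracks, 0)
  st <- step_tracker(st$state, list(list(pose = make_pose(12, 10))))
  expect_equal(st$assignments, 1L)            # ids are never reused
})

test_that("a trained embedder preserves ids through a box-swapping crossing
           where IoU swaps them", {
  fit <- trained_gcn()
  expect_gte(max(fit$accuracy), 0.85)
  # two hands with distinct flexion exchange positions between frames
  an1 <- ht_ns$with_rng_seed(21L, ht_ns$sample_hand_anatomy(30, "right"))
  an2 <- ht_ns$with_rng_seed(22L, ht_ns$sample_hand_anatomy(30, "right"))
  mkpose <- function(an, ctr, phi, tid) {
    xy <- ht_ns$hand_joints(an, ctr, 0, rep(phi, 5))
    b <- c(min(xy[, 1]) - 3, min(xy[, 2]) - 3, max(xy[, 1]) + 3, max(xy[, 2]) + 3)
    hand_pose(xy, rep("visible", 21), "right", b, track_id = tid)
  }
  frame1 <- list(mkpose(an1, c(60, 60), 0.15, 0L), mkpose(an2, c(150, 60), 1.3, 1L))
  # positions swapped; flexion (hence appearance) follows each hand
  frame2 <- list(mkpose(an1, c(150, 60), 0.18, 0L), mkpose(an2, c(60, 60), 1.25, 1L))

  run <- function(strategy, gcn_model = NULL) {
    trk <- new_tracker(strategy, gcn_model = gcn_model)
    s1 <- step_tracker(trk, lapply(frame1, function(p) list(pose = p)))
    s2 <- step_tracker(s1$state, lapply(frame2, function(p) list(pose = p)))
    s2$assignments
  }
  expect_equal(run("iou"), c(1L, 0L))              # boxes teleport: IoU swaps
  expect_equal(run("gcn", fit$model), c(0L, 1L))   # appearance keeps ids
})
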