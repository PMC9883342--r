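# Shared fixtures: hand-built poses/clips, random tracking scenarios, an
# independent brute-force recount of the tracking error counts, and a cache
# for models that several tests share.

ht_ns <- asNamespace("handtrack")

# A deterministic, well-spread 21-joint layout inside a box.
grid_pose_xy <- function(x0 = 10, y0 = 10, w = 40, h = 40) {
  g <- expand.grid(gx = 1:5, gy = 1:5)[1:21, ]
  cbind(x0 + g$gx / 6 * w, y0 + g$gy / 6 * h)
}

make_pose <- function(x0 = 10, y0 = 10, w = 40, h = 40,
                      state = rep("visible", 21), track_id = NULL,
                      confidence = NULL, handedness = "right") {
  hand_pose(xy = grid_pose_xy(x0, y0, w, h), state = state,
            handedness = handedness, box = c(x0, y0, x0 + w, y0 + h),
            track_id = track_id, confidence = confidence)
}

shift_pose <- function(p, dx, dy) {
  p$xy <- p$xy + cbind(rep(dx, 21), rep(dy, 21))
  p$box <- p$box + c(dx, dy, dx, dy)
  p
}

make_clip <- function(frames_hands, clip_id = "fix", fps = 8) {
  frames <- lapply(seq_along(frames_hands), function(k)
    list(frame_index = k - 1L, image = NULL, hands = frames_hands[[k]]))
  clip_annotation(clip_id = clip_id, fps = fps, frames = frames)
}

with_conf <- function(p, conf = rep(1, 21)) {
  p$confidence <- conf
  p
}

# ---- independent brute-force tracking-metrics oracle ------------------------
#
# Recounts FN / FP / IDSW per joint with plain nested loops, straight from
# the definitions: per frame, poses are matched one-to-one by repeatedly
# taking the highest-PCK pair; a gt joint is missed unless its pose is
# matched and the prediction lies within sigma * max-side of the gt box;
# predicted joints of unmatched poses and wrong hypotheses are false
# positives; a matched pose whose predicted id differs from the id
# previously matched to the same gt track switches identity once per
# annotated joint. Kept free of any package internals.
oracle_track_counts <- function(pred_clip, gt_clip, sigma = 0.2) {
  J <- 21L
  FN <- FP <- IDSW <- G <- integer(J)
  last_id <- list()
  gt_frames <- gt_clip$frames
  pred_by_idx <- list()
  for (fr in pred_clip$frames) pred_by_idx[[as.character(fr$frame_index)]] <- fr
  for (gfr in gt_frames) {
    pfr <- pred_by_idx[[as.character(gfr$frame_index)]]
    preds <- if (is.null(pfr)) list() else pfr$hands
    gts <- gfr$hands
    # pairwise PCK by brute force
    np <- length(preds); ng <- length(gts)
    pckm <- matrix(0, max(np, 1), max(ng, 1))
    okm <- array(FALSE, c(max(np, 1), max(ng, 1), J))
    distm <- array(Inf, c(max(np, 1), max(ng, 1), J))
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      g <- gts[[j]]
      thr <- sigma * max(g$box[3] - g$box[1], g$box[4] - g$box[2])
      nann <- 0L; ncor <- 0L
      for (jj in seq_len(J)) {
        if (g$state[jj] == "unannotated") next
        nann <- nann + 1L
        dd <- sqrt(sum((preds[[i]]$xy[jj, ] - g$xy[jj, ])^2))
        distm[i, j, jj] <- dd
        if (preds[[i]]$state[jj] != "unannotated" && dd <= thr) {
          ncor <- ncor + 1L
          okm[i, j, jj] <- TRUE
        }
      }
      pckm[i, j] <- if (nann > 0) ncor / nann else 0
    }
    # greedy matching, highest pck first, zero never matched; ties resolve
    # to the lowest prediction index, then ground-truth index (the
    # documented rule)
    pu <- rep(FALSE, np); gu <- rep(FALSE, ng)
    pairs <- list()
    repeat {
      best <- 0; bi <- 0; bj <- 0
      for (i in seq_len(np)) for (j in seq_len(ng)) {
        if (pu[i] || gu[j]) next
        if (pckm[i, j] > best) { best <- pckm[i, j]; bi <- i; bj <- j }
      }
      if (best <= 0) break
      pu[bi] <- TRUE; gu[bj] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(bi, bj)
    }
    matched_of_gt <- rep(NA_integer_, ng)
    for (pr in pairs) matched_of_gt[pr[2]] <- pr[1]
    for (j in seq_len(ng)) {
      g <- gts[[j]]
      for (jj in seq_len(J)) if (g$state[jj] != "unannotated") G[jj] <- G[jj] + 1L
      i <- matched_of_gt[j]
      if (is.na(i)) {
        for (jj in seq_len(J)) if (g$state[jj] != "unannotated") FN[jj] <- FN[jj] + 1L
        next
      }
      for (jj in seq_len(J)) {
        if (g$state[jj] == "unannotated") next
        if (!okm[i, j, jj]) {
          FN[jj] <- FN[jj] + 1L
          if (preds[[i]]$state[jj] != "unannotated") FP[jj] <- FP[jj] + 1L
        }
      }
      key <- as.character(g$track_id)
      if (!is.null(last_id[[key]]) && last_id[[key]] != preds[[i]]$track_id) {
        for (jj in seq_len(J)) if (g$state[jj] != "unannotated")
          IDSW[jj] <- IDSW[jj] + 1L
      }
      last_id[[key]] <- preds[[i]]$track_id
    }
    for (i in seq_len(np)) {
      if (np == 0 || pu[i]) next
      for (jj in seq_len(J)) if (preds[[i]]$state[jj] != "unannotated")
        FP[jj] <- FP[jj] + 1L
    }
  }
  list(FN = sum(FN), FP = sum(FP), IDSW = sum(IDSW), G = sum(G),
       mota = 100 * (1 - (sum(FN) + sum(FP) + sum(IDSW)) / sum(G)))
}

# Random small tracking scenario: ground truth tracks with noisy, dropped,
# spurious and id-mangled predictions.
random_scenario <- function(seed) {
  set.seed(seed)
  n_tracks <- sample(1:5, 1)
  n_frames <- sample(2:20, 1)
  gt_frames <- vector("list", n_frames)
  pred_frames <- vector("list", n_frames)
  starts <- lapply(1:n_tracks, function(i)
    c(runif(1, 0, 150), runif(1, 0, 150)))
  vel <- lapply(1:n_tracks, function(i) c(runif(1, -4, 4), runif(1, -4, 4)))
  for (t in 1:n_frames) {
    gh <- list(); ph <- list()
    for (i in 1:n_tracks) {
      if (runif(1) < 0.15) next   # gt absent this frame
      pos <- starts[[i]] + (t - 1) * vel[[i]]
      st <- rep("visible", 21)
      st[runif(21) < 0.2] <- "occluded"
      st[runif(21) < 0.1] <- "unannotated"
      if (all(st == "unannotated")) st[1] <- "visible"
      g <- make_pose(pos[1], pos[2], 40, 40, state = st, track_id = i - 1L)
      gh[[length(gh) + 1L]] <- g
      if (runif(1) < 0.2) next    # missed detection
      p <- g
      p$xy <- p$xy + matrix(rnorm(42, 0, 4), 21, 2)
      p$state <- rep("visible", 21)
      p$confidence <- runif(21, 0.3, 1)
      p$track_id <- if (runif(1) < 0.15) i - 1L + 100L else i - 1L  # id mangling
      ph[[length(ph) + 1L]] <- p
    }
    if (runif(1) < 0.25) {        # spurious detection far away
      p <- make_pose(runif(1, 200, 300), runif(1, 200, 300), 40, 40,
                     track_id = 50L + t, confidence = runif(21, 0.3, 1))
      ph[[length(ph) + 1L]] <- p
    }
    gt_frames[[t]] <- gh
    pred_frames[[t]] <- ph
  }
  list(gt = make_clip(gt_frames, sprintf("scn%d", seed)),
       pred = make_clip(pred_frames, sprintf("scn%d", seed)))
}

# ---- shared trained models (built once per test run) ------------------------

.ht_cache <- new.env(parent = emptyenv())

# The 20-clip synthetic tracking dataset used for embedder tests.
gcn_bench_clips <- function() {
  if (!is.null(.ht_cache$gcn_clips)) return(.ht_cache$gcn_clips)
  scfg <- synth_config(n_frames = 8L, seed = 100L)
  counts <- ht_ns$with_rng_seed(101L, ht_ns$stratified_counts(20L))
  clips <- lapply(1:20, function(i) {
    cc <- scfg
    cc$seed <- ht_ns$derive_seed(100L, i)
    cc$n_hands <- counts[i]
    generate_clip(cc, sprintf("c%02d", i))$annotation
  })
  .ht_cache$gcn_clips <- clips
  clips
}

trained_gcn <- function() {
  if (!is.null(.ht_cache$gcn_fit)) return(.ht_cache$gcn_fit)
  clips <- gcn_bench_clips()
  gcfg <- gcn_config(epochs = 20L, seed = 11L)
  fit <- train_gcn(clips[1:16], gcfg, eval_clips = clips[17:20])
  .ht_cache$gcn_fit <- fit
  fit
}
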