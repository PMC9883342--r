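# Conditional prediction head: curriculum, prior selection, forward
# contracts, candidate selection, ablations and finetuning.

small_pose_cfg <- function() posenet_config(input_size = c(32L, 32L),
                                            heatmap_size = c(16L, 16L), seed = 9L)

test_that("the curriculum ramps linearly and saturates", {
  cfg <- cond_config()
  expect_equal(curriculum_prob(0, cfg), 0)
  expect_equal(curriculum_prob(5, cfg), 0.5)
  expect_equal(curriculum_prob(10, cfg), 1)
  expect_equal(curriculum_prob(12, cfg), 1)
  expect_equal(cfg$curriculum_slope * cfg$saturation_epoch, 1.0)
  expect_error(curriculum_prob(-1, cfg), class = "ht_schema_error")
  slow <- cond_config(curriculum_slope = 0.05, saturation_epoch = 20L)
  expect_equal(curriculum_prob(10, slow), 0.5)
})

test_that("prior selection follows the delta-then-fallback rule", {
  grid <- c(16L, 16L)
  mk <- function(v) heatmap_stack(array(v, c(21, grid[1], grid[2])))
  tr <- new_track()
  # no history at all -> zeros
  pr <- select_prior(tr, 0L, 3L, grid)
  expect_true(is.na(pr$frame))
  expect_equal(sum(pr$heatmaps$values), 0)
  # present exactly at t - delta
  tr <- track_store(tr, 4L, mk(0.4))
  tr <- track_store(tr, 5L, mk(0.5))
  tr <- track_store(tr, 6L, mk(0.6))
  expect_equal(select_prior(tr, 7L, 3L, grid)$frame, 4L)
  # absent at t-3 but present at t-2 and t-1 -> nearest-to-t-delta, i.e. t-2
  tr2 <- new_track()
  tr2 <- track_store(tr2, 5L, mk(0.5))
  tr2 <- track_store(tr2, 6L, mk(0.6))
  expect_equal(select_prior(tr2, 7L, 3L, grid)$frame, 5L)
  # only frames before t-delta -> scan backwards to first occurrence
  tr3 <- new_track()
  tr3 <- track_store(tr3, 1L, mk(0.1))
  expect_equal(select_prior(tr3, 7L, 3L, grid)$frame, 1L)
  expect_error(select_prior(tr, 7L, 0L, grid), class = "ht_schema_error")
})

test_that("conditional forward meets shape/determinism contracts on the zeros prior", {
  pm <- posenet_init(small_pose_cfg())
  cm <- condpose_init(pm, cond_config(seed = 2L))
  crop <- array(runif(32 * 32 * 3), c(32, 32, 3))
  zp <- handtrack:::zeros_heatmap(c(16L, 16L))
  o1 <- condpose_forward(cm, crop, zp)
  expect_equal(dim(o1$heatmaps$values), c(21, 16, 16))
  expect_true(all(is.finite(o1$heatmaps$values)))
  o2 <- condpose_forward(cm, crop, zp)
  expect_identical(o1$heatmaps$values, o2$heatmaps$values)
  bad <- handtrack:::zeros_heatmap(c(8L, 8L))
  expect_error(condpose_forward(cm, crop, bad), class = "ht_schema_error")
})

test_that("with fusion weights that copy the initial estimate, the conditional
           model reproduces the baseline pathway", {
  pm <- posenet_init(small_pose_cfg())
  cm <- condpose_init(pm, cond_config(fus_hidden = 42L, seed = 3L))
  J <- 21L
  # fus1: hidden j = relu(Hp_j), hidden J+j = relu(-Hp_j), via the center tap
  W1 <- matrix(0, 42, 42 * 9)
  center <- 4L * 42L   # offset of the (dr=0, dc=0) tap block
  for (j in 1:J) {
    W1[j, center + j] <- 1
    W1[J + j, center + j] <- -1
  }
  W2 <- matrix(0, J, 42 * 9)
  center2 <- 4L * 42L
  for (j in 1:J) {
    W2[j, center2 + j] <- 1
    W2[j, center2 + J + j] <- -1
  }
  cm$par$fus1 <- list(W = W1, b = numeric(42))
  cm$par$fus2 <- list(W = W2, b = numeric(J))
  crop <- array(runif(32 * 32 * 3), c(32, 32, 3))
  prior <- heatmap_stack(array(rnorm(21 * 16 * 16), c(21, 16, 16)))
  out <- condpose_forward(cm, crop, prior)
  base <- pose_forward(pm, crop)
  expect_equal(out$heatmaps$values, base$heatmaps$values, tolerance = 1e-12)
  expect_equal(out$initial$values, base$heatmaps$values, tolerance = 1e-12)
})

test_that("ablation variants have distinct, strictly smaller parameter counts", {
  pm <- posenet_init(small_pose_cfg())
  full <- condpose_init(pm, cond_config(seed = 1L))
  nc <- condpose_init(pm, cond_config(use_feature_map = FALSE, seed = 1L))
  na <- condpose_init(pm, cond_config(use_attention = FALSE, seed = 1L))
  ncna <- condpose_init(pm, cond_config(use_attention = FALSE,
                                        use_feature_map = FALSE, seed = 1L))
  counts <- c(full = n_params(full), nc = n_params(nc), na = n_params(na),
              ncna = n_params(ncna))
  expect_equal(length(unique(counts)), 4)
  expect_true(all(counts[-1] < counts["full"]))
  # every variant still runs forward and differs from the full model
  crop <- array(runif(32 * 32 * 3), c(32, 32, 3))
  zp <- handtrack:::zeros_heatmap(c(16L, 16L))
  for (m in list(nc, na, ncna)) {
    o <- condpose_forward(m, crop, zp)
    expect_true(all(is.finite(o$heatmaps$values)))
  }
})

test_that("candidate selection picks the highest mean-max confidence and is
           invariant to prior ordering", {
  pm <- posenet_init(small_pose_cfg())
  cm <- condpose_init(pm, cond_config(seed = 6L))
  crop <- array(runif(32 * 32 * 3), c(32, 32, 3))
  mk <- function(s) heatmap_stack(array(runif(21 * 16 * 16, 0, s), c(21, 16, 16)))
  set.seed(3)
  priors <- list(mk(0.5), mk(1.2), mk(0.8))
  dets <- list(list(crop = crop))
  res <- infer_frame(cm, dets, priors)[[1]]
  # recompute every candidate by hand: priors 1..3 then the zeros prior
  cands <- c(priors, list(handtrack:::zeros_heatmap(c(16L, 16L))))
  scores <- vapply(cands, function(p)
    handtrack:::mean_max_confidence(condpose_forward(cm, crop, p)$heatmaps), 0)
  expect_equal(res$confidence, max(scores))
  best <- which.max(scores)
  expect_equal(if (is.na(res$prior_index)) 4L else res$prior_index, best)

  perm <- c(3L, 1L, 2L)
  res_p <- infer_frame(cm, dets, priors[perm])[[1]]
  expect_equal(res_p$heatmaps$values, res$heatmaps$values)
  if (!is.na(res$prior_index)) {
    expect_equal(perm[res_p$prior_index], res$prior_index)
  }

  # no priors: zeros prior is used
  res0 <- infer_frame(cm, dets, list())[[1]]
  expect_true(is.na(res0$prior_index))
  expect_equal(length(infer_frame(cm, list(), priors)), 0)
})

test_that("finetuning obeys the curriculum bookkeeping and reduces the loss", {
  clips <- lapply(1:3, function(i)
    generate_clip(synth_config(n_frames = 5L, n_hands = 2L, image_size = c(96L, 96L),
                               seed = 500L + i), sprintf("c%d", i)))
  pcfg <- posenet_config(seed = 12L)
  pm <- posenet_init(pcfg)

  # slope 0, saturation far away: ground-truth priors only
  fit_gt <- train_condpose(clips[1], pm, cond_config(
    epochs = 2L, curriculum_slope = 0, saturation_epoch = 100L, seed = 1L))
  expect_equal(sum(fit_gt$prior_stats[, "pred"]), 0)

  # saturation at epoch 0: predicted priors only
  fit_pred <- train_condpose(clips[1], pm, cond_config(
    epochs = 2L, saturation_epoch = 0L, seed = 1L))
  expect_equal(sum(fit_pred$prior_stats[, "gt"]), 0)

  fit <- train_condpose(clips, pm, cond_config(epochs = 3L, seed = 2L))
  expect_lt(fit$history[3], fit$history[1])

  untracked <- clips[1]
  untracked[[1]]$annotation$frames[[1]]$hands[[1]]$track_id <- NULL
  expect_error(train_condpose(untracked, pm, cond_config(epochs = 1L)),
               class = "ht_schema_error")
})
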