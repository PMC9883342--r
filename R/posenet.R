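# Frame-wise pose estimation network P: crop in, per-joint heatmaps out.
#
# Desk-scale convolutional encoder-decoders stand in for large pretrained
# backbones; the conditional mechanism layered on top (see condpose.R) is
# backbone-agnostic. "tiny" has stride 2 (one pooling stage), "small" stride
# 4 (two pooling stages). The first conv block's activations double as the
# image feature map v_t consumed by the conditional attention head.

BACKBONES <- list(
  tiny = list(stride = 2L, f1 = 8L, f2 = 16L, f3 = 16L),
  small = list(stride = 4L, f1 = 12L, f2 = 24L, f3 = 24L))

#' Pose network configuration
#'
#' @param backbone `"tiny"` (stride 2) or `"small"` (stride 4).
#' @param input_size crop size `c(H, W)` fed to the network.
#' @param heatmap_size output heatmap grid `c(H', W')`; must equal
#'   `input_size / stride`.
#' @param J number of joints.
#' @param batch_size minibatch size (default 16).
#' @param epochs training epochs (default 30).
#' @param lr Adam learning rate (default 1e-3).
#' @param sigma_hm ground-truth Gaussian width in heatmap pixels.
#' @param augment apply random rotations and horizontal flips.
#' @param rotation_range maximum absolute rotation in radians (default 30 deg).
#' @param seed integer seed for initialization and the training loop.
#' @return object of class `posenet_config`.
#' @export
posenet_config <- function(backbone = "tiny", input_size = c(64L, 64L),
                           heatmap_size = c(32L, 32L), J = HT_J,
                           batch_size = 16L, epochs = 30L, lr = 1e-3,
                           sigma_hm = 2, augment = TRUE,
                           rotation_range = pi / 6, seed = 1L) {
  if (!backbone %in% names(BACKBONES))
    abort_ht("unknown backbone", "ht_schema_error")
  st <- BACKBONES[[backbone]]$stride
  if (!all(input_size == heatmap_size * st))
    abort_ht(sprintf("heatmap_size must be input_size / %d for backbone '%s'",
                     st, backbone), "ht_schema_error")
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 heatmap_size = as.integer(heatmap_size), J = as.integer(J),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = lr, sigma_hm = sigma_hm, augment = isTRUE(augment),
                 rotation_range = rotation_range, seed = as.integer(seed)),
            class = "posenet_config")
}

#' Initialize a pose network with random weights
#' @param cfg a [posenet_config()].
#' @return object of class `posenet_model`.
#' @export
posenet_init <- function(cfg) {
  bb <- BACKBONES[[cfg$backbone]]
  par <- with_rng_seed(derive_seed(cfg$seed, 1L), list(
    c1 = conv3_new(3L, bb$f1),
    c2 = conv3_new(bb$f1, bb$f2),
    c3 = conv3_new(bb$f2, bb$f3),
    c4 = conv3_new(bb$f3, cfg$J, gain = 1)))
  structure(list(cfg = cfg, par = par), class = "posenet_model")
}

image_to_chw <- function(img) aperm(img, c(3, 1, 2)) - 0.5

# Full forward pass with caches kept for backprop.
posenet_fwd_full <- function(model, x) {
  p <- model$par
  bb <- BACKBONES[[model$cfg$backbone]]
  f1 <- conv3_fwd(p$c1, x); a1 <- relu_fwd(f1$y)
  p1 <- maxpool2_fwd(a1)
  h <- p1$y
  p2 <- NULL
  f2 <- conv3_fwd(p$c2, h); a2 <- relu_fwd(f2$y)
  h <- a2
  if (bb$stride == 4L) { p2 <- maxpool2_fwd(a2); h <- p2$y }
  f3 <- conv3_fwd(p$c3, h); a3 <- relu_fwd(f3$y)
  f4 <- conv3_fwd(p$c4, a3)
  list(H = f4$y, v = a1,
       cache = list(f1 = f1, p1 = p1, f2 = f2, p2 = p2, f3 = f3, f4 = f4,
                    a3 = a3))
}

# Backward pass; dH is the gradient on the output heatmaps, dv an optional
# gradient injected on the feature map v_t (from the conditional head).
posenet_bwd_full <- function(model, fw, dH, dv = NULL) {
  p <- model$par
  bb <- BACKBONES[[model$cfg$backbone]]
  cc <- fw$cache
  b4 <- conv3_bwd(p$c4, cc$f4, dH)
  dz3 <- relu_bwd(cc$f3$y, b4$dx)
  b3 <- conv3_bwd(p$c3, cc$f3, dz3)
  da2 <- b3$dx
  if (bb$stride == 4L) da2 <- maxpool2_bwd(cc$p2, da2)
  dz2 <- relu_bwd(cc$f2$y, da2)
  b2 <- conv3_bwd(p$c2, cc$f2, dz2)
  da1 <- maxpool2_bwd(cc$p1, b2$dx)
  if (!is.null(dv)) da1 <- da1 + dv
  dz1 <- relu_bwd(cc$f1$y, da1)
  b1 <- conv3_bwd(p$c1, cc$f1, dz1, need_dx = FALSE)
  list(c1 = b1$grad, c2 = b2$grad, c3 = b3$grad, c4 = b4$grad)
}

#' Run the pose network on one crop
#'
#' @param model a `posenet_model`.
#' @param crop H x W x 3 crop image in `[0, 1]` matching the configured
#'   input size.
#' @return list with `heatmaps` (a [heatmap_stack()], all channels
#'   masked-in) and `v` (the early feature map, channels x H x W).
#' @export
pose_forward <- function(model, crop) {
  d <- dim(crop)
  if (d[1] != model$cfg$input_size[1] || d[2] != model$cfg$input_size[2])
    abort_ht("crop size does not match the configured input size", "ht_schema_error")
  fw <- posenet_fwd_full(model, image_to_chw(crop))
  list(heatmaps = heatmap_stack(fw$H), v = fw$v)
}

# Gaussian ground-truth stack from crop-space keypoints.
encode_from_crop_xy <- function(xy_crop, state, input_size, grid, sigma_hm) {
  J <- nrow(xy_crop)
  vals <- array(0, c(J, grid[1], grid[2]))
  mask <- rep(FALSE, J)
  gx <- (xy_crop[, 1] + 0.5) / input_size[2] * grid[2] - 0.5
  gy <- (xy_crop[, 2] + 0.5) / input_size[1] * grid[1] - 0.5
  cols <- seq_len(grid[2]) - 1L
  rows <- seq_len(grid[1]) - 1L
  for (j in seq_len(J)) {
    if (state[j] == "unannotated") next
    c0 <- round(gx[j]); r0 <- round(gy[j])
    if (!is.finite(c0) || !is.finite(r0) ||
        c0 < 0 || c0 > grid[2] - 1L || r0 < 0 || r0 > grid[1] - 1L) next
    mask[j] <- TRUE
    vals[j, , ] <- exp(-(outer((rows - r0)^2, (cols - c0)^2, "+")) / (2 * sigma_hm^2))
  }
  heatmap_stack(vals, mask)
}

#' Extract (crop, pose) training samples from a clip
#'
#' Crops every annotated hand at the configured scale factor and input size.
#'
#' @param clip a [clip_annotation()].
#' @param frames list of frame images aligned with `clip$frames`.
#' @param cfg a [posenet_config()].
#' @param scale_factor crop area ratio (default 2.2).
#' @return list of samples, each with `crop`, `geom`, `pose`, `xy_crop`,
#'   `state`, `frame_index` and `track_id`.
#' @export
crop_samples_from_clip <- function(clip, frames, cfg, scale_factor = 2.2) {
  out <- list()
  for (k in seq_along(clip$frames)) {
    fr <- clip$frames[[k]]
    for (h in fr$hands) {
      cr <- make_crop(frames[[k]], h$box, scale_factor, cfg$input_size)
      out[[length(out) + 1L]] <- list(
        crop = cr$image, geom = cr$geom, pose = h,
        xy_crop = frame_to_crop(cr$geom, h$xy), state = h$state,
        frame_index = fr$frame_index, track_id = h$track_id)
    }
  }
  out
}

augment_sample <- function(sample, cfg) {
  crop <- sample$crop; xy <- sample$xy_crop
  if (stats::runif(1) < 0.5) {
    fl <- flip_crop(crop, xy)
    crop <- fl$image; xy <- fl$xy
  }
  ang <- stats::runif(1, -cfg$rotation_range, cfg$rotation_range)
  rt <- rotate_crop(crop, xy, ang)
  list(crop = rt$image, xy_crop = rt$xy, state = sample$state)
}

#' Train the pose network
#'
#' Minimizes the masked MSE between predicted and Gaussian ground-truth
#' heatmaps with Adam, optionally applying random rotations and horizontal
#' flips (a flip mirrors x and swaps the handedness semantics; the per-finger
#' joint order needs no permutation).
#'
#' @param samples list of samples from [crop_samples_from_clip()].
#' @param cfg a [posenet_config()].
#' @param model optional model to continue training (default: fresh init).
#' @return list with `model` and `history` (per-epoch mean loss).
#' @export
train_posenet <- function(samples, cfg, model = NULL) {
  if (length(samples) == 0) abort_ht("empty training set", "ht_schema_error")
  if (is.null(model)) model <- posenet_init(cfg)
  flat <- flatten_params(model$par)
  opt <- adam_new(flat)
  history <- numeric(cfg$epochs)
  with_rng_seed(derive_seed(cfg$seed, 2L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(samples))
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        gacc <- NULL
        for (i in idx) {
          s <- samples[[i]]
          if (cfg$augment) s <- c(augment_sample(samples[[i]], cfg), samples[[i]]["geom"])
          gt <- encode_from_crop_xy(s$xy_crop, s$state, cfg$input_size,
                                    cfg$heatmap_size, cfg$sigma_hm)
          fw <- posenet_fwd_full(model, image_to_chw(s$crop))
          pred <- heatmap_stack(fw$H)
          ep_loss <- ep_loss + masked_mse(pred, gt)
          dH <- masked_mse_grad(pred, gt)
          g <- flatten_params(posenet_bwd_full(model, fw, dH))
          gacc <- if (is.null(gacc)) g else acc_grads(gacc, g)
        }
        gacc <- scale_grads(gacc, 1 / length(idx))
        stp <- adam_step(flat, gacc, opt, cfg$lr)
        flat <- stp$params; opt <- stp$state
        model$par <- unflatten_params(flat)
        nb <- nb + length(idx)
      }
      history[ep] <- ep_loss / nb
    }
  })
  list(model = model, history = history)
}

#' Save a model checkpoint
#' @param model a `posenet_model`, `condpose_model` or `gcn_model`.
#' @param path output path.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "handtrack-ckpt-v1", type = class(model)[1],
              model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path checkpoint path from [save_checkpoint()].
#' @return the stored model object.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "handtrack-ckpt-v1"))
    abort_ht("not a handtrack checkpoint", "ht_io_error")
  obj$model
}
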