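# Conditional pose prediction: the current crop's initial heatmap estimate is
# fused with an attention-weighted heatmap prior carried forward from an
# earlier frame (t - delta) of the same track.
#
#   H_t = M_fus( P(I_t) ; M_att(v_t ; H_{t-delta}) )
#
# M_att sees the early conv feature map v_t (resized to the heatmap grid)
# concatenated with the prior and outputs a re-weighted prior; M_fus merges
# the initial estimate with the weighted prior into the final heatmaps.
# Ablation switches: use_feature_map = FALSE (NC) hides v_t from M_att;
# use_attention = FALSE (NA) removes M_att, the fusion then consuming the raw
# prior (and, when the feature map is enabled, v_t directly).

#' Conditional head configuration
#'
#' @param delta temporal gap of the prior in frames (default 3).
#' @param use_attention enable the attention branch M_att (disable for the
#'   NA ablation).
#' @param use_feature_map feed the conv feature map into the head (disable
#'   for the NC ablation).
#' @param curriculum_slope per-epoch increase of the probability of training
#'   with predicted (rather than ground-truth) priors; default 0.10/epoch.
#' @param saturation_epoch epoch from which only predicted priors are used
#'   (default 10; with the default slope the schedule reaches 1.0 exactly
#'   there).
#' @param epochs finetuning epochs.
#' @param lr Adam learning rate.
#' @param batch_size gradient accumulation batch.
#' @param att_hidden,fus_hidden hidden channel widths of M_att / M_fus.
#' @param include_zero_prior also score a zeros prior among inference
#'   candidates, so hands entering the scene are not forced onto a stale
#'   prior.
#' @param seed integer seed.
#' @return object of class `cond_config`.
#' @export
cond_config <- function(delta = 3L, use_attention = TRUE, use_feature_map = TRUE,
                        curriculum_slope = 0.10, saturation_epoch = 10L,
                        epochs = 10L, lr = 1e-3, batch_size = 16L,
                        att_hidden = 16L, fus_hidden = 32L,
                        include_zero_prior = TRUE, seed = 1L) {
  if (delta < 1L) abort_ht("delta must be >= 1", "ht_schema_error")
  structure(list(delta = as.integer(delta), use_attention = isTRUE(use_attention),
                 use_feature_map = isTRUE(use_feature_map),
                 curriculum_slope = curriculum_slope,
                 saturation_epoch = as.integer(saturation_epoch),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 att_hidden = as.integer(att_hidden),
                 fus_hidden = as.integer(fus_hidden),
                 include_zero_prior = isTRUE(include_zero_prior),
                 seed = as.integer(seed)),
            class = "cond_config")
}

#' Probability of sampling a predicted prior at a given epoch
#'
#' The curriculum ramps linearly from ground-truth priors towards the
#' model's own predictions: `p = min(slope * epoch, 1)`, clamped to 1 from
#' the saturation epoch onwards.
#'
#' @param epoch zero-based epoch index.
#' @param config a [cond_config()].
#' @return probability in `[0, 1]`.
#' @export
curriculum_prob <- function(epoch, config = cond_config()) {
  if (epoch < 0) abort_ht("epoch must be >= 0", "ht_schema_error")
  if (epoch >= config$saturation_epoch) return(1)
  min(config$curriculum_slope * epoch, 1)
}

# ---- track prior bookkeeping ------------------------------------------------

#' Create an empty track history
#' @return object of class `ht_track` storing per-frame heatmaps.
#' @export
new_track <- function() {
  structure(list(entries = list()), class = "ht_track")
}

#' Store a track's heatmap for one frame
#' @param track an `ht_track`.
#' @param frame integer frame index.
#' @param heatmaps the [heatmap_stack()] predicted (or encoded) for the
#'   track at that frame.
#' @return the updated track.
#' @export
track_store <- function(track, frame, heatmaps) {
  track$entries[[as.character(frame)]] <- heatmaps
  track
}

track_frames <- function(track) sort(as.integer(names(track$entries)))

#' Select the heatmap prior for frame t from a track's history
#'
#' Returns the heatmap stored at `t - delta` when present. Otherwise frames
#' nearer to `t` are scanned first (`t - delta + 1`, ..., `t - 1`), then
#' earlier frames (`t - delta - 1` backwards to the track's first
#' occurrence); if the track has no stored frame before `t`, an all-zeros
#' prior is returned.
#'
#' @param track an `ht_track`.
#' @param t current frame index.
#' @param delta temporal gap.
#' @param grid heatmap grid `c(H', W')` used for the zeros fallback.
#' @param J number of joints.
#' @return list with `heatmaps` and `frame` (`NA` for the zeros prior).
#' @export
select_prior <- function(track, t, delta, grid = c(32L, 32L), J = HT_J) {
  if (delta < 1L) abort_ht("delta must be >= 1", "ht_schema_error")
  avail <- track_frames(track)
  avail <- avail[avail < t]
  target <- t - delta
  nearer <- if (target + 1L <= t - 1L) (target + 1L):(t - 1L) else integer(0)
  earlier <- if (target - 1L >= 0L) (target - 1L):0L else integer(0)
  for (f in c(target, nearer, earlier)) {
    if (f %in% avail) {
      return(list(heatmaps = track$entries[[as.character(f)]], frame = f))
    }
  }
  list(heatmaps = zeros_heatmap(grid, J), frame = NA_integer_)
}

# ---- model ------------------------------------------------------------------

#' Initialize a conditional pose model from a pose network
#'
#' Copies the backbone weights and adds the attention / fusion head for the
#' configured ablation variant.
#'
#' @param pose_model a trained (or fresh) `posenet_model`.
#' @param ccfg a [cond_config()].
#' @return object of class `condpose_model`.
#' @export
condpose_init <- function(pose_model, ccfg) {
  cfg <- pose_model$cfg
  f1 <- BACKBONES[[cfg$backbone]]$f1
  J <- cfg$J
  par <- pose_model$par
  with_rng_seed(derive_seed(ccfg$seed, 3L), {
    if (ccfg$use_attention) {
      ain <- if (ccfg$use_feature_map) f1 + J else J
      par$att1 <- conv3_new(ain, ccfg$att_hidden)
      par$att2 <- conv3_new(ccfg$att_hidden, J, gain = 1)
    }
    fin <- if (ccfg$use_attention) 2L * J
    else if (ccfg$use_feature_map) 2L * J + f1
    else 2L * J
    # NC-NA and NA differ in fusion input channels; full/NC share fin = 2J
    par$fus1 <- conv3_new(fin, ccfg$fus_hidden)
    par$fus2 <- conv3_new(ccfg$fus_hidden, J, gain = 1)
  })
  structure(list(cfg = cfg, ccfg = ccfg, par = par), class = "condpose_model")
}

#' Total number of trainable parameters
#' @param model any model in this package.
#' @return integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$par, function(l) sum(vapply(l, length, 0L)), 0L))
}

condpose_fwd_full <- function(model, x, prior) {
  ccfg <- model$ccfg
  p <- model$par
  stride <- BACKBONES[[model$cfg$backbone]]$stride
  bb <- posenet_fwd_full(model, x)
  vr <- downsample_mean_fwd(bb$v, stride)
  J <- model$cfg$J
  att <- NULL
  if (ccfg$use_attention) {
    att_in <- if (ccfg$use_feature_map) cat_channels(vr, prior$values) else prior$values
    fa1 <- conv3_fwd(p$att1, att_in); aa1 <- relu_fwd(fa1$y)
    fa2 <- conv3_fwd(p$att2, aa1)
    Hw <- fa2$y
    att <- list(fa1 = fa1, fa2 = fa2)
    fus_in <- cat_channels(bb$H, Hw)
  } else if (ccfg$use_feature_map) {
    fus_in <- cat_channels(bb$H, vr, prior$values)
  } else {
    fus_in <- cat_channels(bb$H, prior$values)
  }
  ff1 <- conv3_fwd(p$fus1, fus_in); af1 <- relu_fwd(ff1$y)
  ff2 <- conv3_fwd(p$fus2, af1)
  list(H = ff2$y, Hp = bb$H, bb = bb, vr = vr, att = att,
       ff1 = ff1, ff2 = ff2)
}

condpose_bwd_full <- function(model, fw, dH) {
  ccfg <- model$ccfg
  p <- model$par
  stride <- BACKBONES[[model$cfg$backbone]]$stride
  J <- model$cfg$J
  f1 <- BACKBONES[[model$cfg$backbone]]$f1
  bf2 <- conv3_bwd(p$fus2, fw$ff2, dH)
  dz1 <- relu_bwd(fw$ff1$y, bf2$dx)
  bf1 <- conv3_bwd(p$fus1, fw$ff1, dz1)
  grads <- list(fus1 = bf1$grad, fus2 = bf2$grad)
  dvr <- NULL
  if (ccfg$use_attention) {
    parts <- split_channels(bf1$dx, c(J, J))
    dHp <- parts[[1]]; dHw <- parts[[2]]
    ba2 <- conv3_bwd(p$att2, fw$att$fa2, dHw)
    dza1 <- relu_bwd(fw$att$fa1$y, ba2$dx)
    ba1 <- conv3_bwd(p$att1, fw$att$fa1, dza1)
    grads$att1 <- ba1$grad; grads$att2 <- ba2$grad
    if (ccfg$use_feature_map) dvr <- split_channels(ba1$dx, c(f1, J))[[1]]
  } else if (ccfg$use_feature_map) {
    parts <- split_channels(bf1$dx, c(J, f1, J))
    dHp <- parts[[1]]; dvr <- parts[[2]]
  } else {
    dHp <- split_channels(bf1$dx, c(J, J))[[1]]
  }
  dv <- if (is.null(dvr)) NULL else
    downsample_mean_bwd(dvr, stride, dim(fw$bb$v))
  bbg <- posenet_bwd_full(model, fw$bb, dHp, dv)
  c(bbg, grads)
}

#' Conditional forward pass for one crop and one prior
#'
#' @param model a `condpose_model`.
#' @param crop H x W x 3 crop image in `[0, 1]`.
#' @param prior a [heatmap_stack()] prior (all-zeros for a track with no
#'   history), on the model's heatmap grid.
#' @return list with `heatmaps` (the fused [heatmap_stack()]) and `initial`
#'   (the unconditioned estimate from the backbone).
#' @export
condpose_forward <- function(model, crop, prior) {
  d <- dim(prior$values)
  if (!all(d[2:3] == model$cfg$heatmap_size))
    abort_ht("prior grid does not match the model's heatmap grid", "ht_schema_error")
  fw <- condpose_fwd_full(model, image_to_chw(crop), prior)
  list(heatmaps = heatmap_stack(fw$H), initial = heatmap_stack(fw$Hp))
}

mean_max_confidence <- function(stack) {
  mean(apply(stack$values, 1, max))
}

#' Conditional inference for all detections of one frame
#'
#' Each detection is paired with every candidate prior (all track priors,
#' plus a zeros prior when configured or when no priors exist); the fused
#' heatmaps with the highest mean over joints of the per-joint maximum
#' response win. Ties keep the lowest prior index, with the zeros prior
#' ranked last.
#'
#' @param model a `condpose_model`.
#' @param detections list of detections, each a list with `crop` (and
#'   typically `geom`, `box`).
#' @param priors list of [heatmap_stack()] priors from the previous frame's
#'   tracks.
#' @return list per detection: `heatmaps`, `prior_index` (`NA` for the zeros
#'   prior) and `confidence` (the winning mean-max score).
#' @export
infer_frame <- function(model, detections, priors) {
  grid <- model$cfg$heatmap_size
  J <- model$cfg$J
  cand_priors <- priors
  idxs <- seq_along(priors)
  if (model$ccfg$include_zero_prior || length(priors) == 0L) {
    cand_priors <- c(cand_priors, list(zeros_heatmap(grid, J)))
    idxs <- c(idxs, NA_integer_)
  }
  lapply(detections, function(det) {
    best <- NULL
    for (k in seq_along(cand_priors)) {
      out <- condpose_forward(model, det$crop, cand_priors[[k]])
      sc <- mean_max_confidence(out$heatmaps)
      if (is.null(best) || sc > best$confidence) {
        best <- list(heatmaps = out$heatmaps, prior_index = idxs[k], confidence = sc)
      }
    }
    best
  })
}

#' Finetune the conditional model on tracked clips
#'
#' Clips are processed frame by frame; for each annotated hand the prior is
#' the track's ground-truth heatmap at `t - delta` with probability
#' `1 - p(epoch)` and the model's own stored prediction otherwise, following
#' the curriculum schedule. Augmentation (flip, rotation) is drawn once per
#' clip pass so prior and current frames stay geometrically consistent.
#'
#' @param clips list of clips, each a list with `annotation` and `frames`
#'   (as returned by [read_clip_dir()] or [generate_clip()]).
#' @param pose_model pretrained `posenet_model` used for initialization, or
#'   a `condpose_model` to continue training.
#' @param ccfg a [cond_config()].
#' @return list with `model`, `history` (per-epoch loss), and `prior_stats`
#'   (per-epoch counts of ground-truth vs predicted priors used).
#' @export
train_condpose <- function(clips, pose_model, ccfg) {
  if (length(clips) == 0) abort_ht("empty clip set", "ht_schema_error")
  for (cl in clips) {
    has_ids <- all(vapply(cl$annotation$frames, function(f)
      all(vapply(f$hands, function(h) !is.null(h$track_id), TRUE)), TRUE))
    if (!has_ids) abort_ht("clips must carry track ids", "ht_schema_error")
  }
  model <- if (inherits(pose_model, "condpose_model")) pose_model
  else condpose_init(pose_model, ccfg)
  cfg <- model$cfg
  grid <- cfg$heatmap_size
  flat <- flatten_params(model$par)
  opt <- adam_new(flat)
  history <- numeric(ccfg$epochs)
  prior_stats <- matrix(0L, ccfg$epochs, 2,
                        dimnames = list(NULL, c("gt", "pred")))
  with_rng_seed(derive_seed(ccfg$seed, 4L), {
    for (ep in seq_len(ccfg$epochs)) {
      p_pred <- curriculum_prob(ep - 1L, ccfg)
      ep_loss <- 0; nseen <- 0L
      gacc <- NULL; nacc <- 0L
      for (cl in clips) {
        ann <- cl$annotation
        do_flip <- stats::runif(1) < 0.5
        ang <- stats::runif(1, -cfg$rotation_range, cfg$rotation_range)
        gt_tracks <- list()    # track id -> ht_track of GT heatmaps
        pr_tracks <- list()    # track id -> ht_track of predicted heatmaps
        for (k in seq_along(ann$frames)) {
          fr <- ann$frames[[k]]
          t <- fr$frame_index
          for (h in fr$hands) {
            cr <- make_crop(cl$frames[[k]], h$box, 2.2, cfg$input_size)
            xyc <- frame_to_crop(cr$geom, h$xy)
            crop <- cr$image
            if (do_flip) {
              fl <- flip_crop(crop, xyc); crop <- fl$image; xyc <- fl$xy
            }
            rt <- rotate_crop(crop, xyc, ang)
            crop <- rt$image; xyc <- rt$xy
            gt <- encode_from_crop_xy(xyc, h$state, cfg$input_size, grid, cfg$sigma_hm)
            tid <- as.character(h$track_id)
            gt_tr <- gt_tracks[[tid]] %||% new_track()
            pr_tr <- pr_tracks[[tid]] %||% new_track()
            use_pred <- stats::runif(1) < p_pred
            prior <- if (use_pred) select_prior(pr_tr, t, ccfg$delta, grid, cfg$J)
            else select_prior(gt_tr, t, ccfg$delta, grid, cfg$J)
            ptype <- if (use_pred) "pred" else "gt"
            prior_stats[ep, ptype] <- prior_stats[ep, ptype] + 1L
            fw <- condpose_fwd_full(model, image_to_chw(crop), prior$heatmaps)
            pred <- heatmap_stack(fw$H)
            ep_loss <- ep_loss + masked_mse(pred, gt)
            nseen <- nseen + 1L
            dH <- masked_mse_grad(pred, gt)
            g <- flatten_params(condpose_bwd_full(model, fw, dH))
            gacc <- if (is.null(gacc)) g else acc_grads(gacc, g)
            nacc <- nacc + 1L
            if (nacc >= ccfg$batch_size) {
              stp <- adam_step(flat, scale_grads(gacc, 1 / nacc), opt, ccfg$lr)
              flat <- stp$params; opt <- stp$state
              model$par <- unflatten_params(flat)
              gacc <- NULL; nacc <- 0L
            }
            gt_tracks[[tid]] <- track_store(gt_tr, t, gt)
            pr_tracks[[tid]] <- track_store(pr_tr, t, pred)
          }
        }
      }
      if (nacc > 0L) {
        stp <- adam_step(flat, scale_grads(gacc, 1 / nacc), opt, ccfg$lr)
        flat <- stp$params; opt <- stp$state
        model$par <- unflatten_params(flat)
      }
      history[ep] <- ep_loss / max(1L, nseen)
    }
  })
  list(model = model, history = history, prior_stats = prior_stats)
}
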