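# Orchestration: run tracking over a clip, evaluate predictions against
# ground truth, and the end-to-end demo pipeline on generated data. Every
# run writes a manifest (config hash, seed, versions) sufficient to
# reproduce its outputs bit for bit.

#' Load the clips of a generated dataset into memory
#'
#' @param dataset_dir directory written by [generate_dataset()].
#' @param split `"train"`, `"val"` or `NULL` for all clips.
#' @return list of clips, each with `annotation` and `frames`.
#' @export
load_dataset_clips <- function(dataset_dir, split = NULL) {
  man <- load_manifest(dataset_dir)
  out <- list()
  for (e in man$clips) {
    if (!is.null(split) && !identical(e$split, split)) next
    out[[length(out) + 1L]] <- read_clip_dir(file.path(dataset_dir, e$dir))
  }
  out
}

# Predicted hand_pose from decoded heatmaps.
decoded_to_pose <- function(dec, box, handedness = "right", track_id = NULL) {
  hand_pose(xy = dec$xy, state = rep("visible", HT_J), handedness = handedness,
            box = as.numeric(box), track_id = track_id,
            confidence = pmin(pmax(dec$confidence, 0), 1))
}

#' Track hand poses through one clip
#'
#' Runs per-frame conditional (or frame-independent) pose inference on
#' detected boxes and links detections into tracks.
#'
#' @param clip list with `annotation` and `frames` (see [read_clip_dir()]).
#' @param model a `condpose_model` (conditional inference over track priors)
#'   or a `posenet_model` (frame-independent baseline).
#' @param boxes `"gt"` for perfect detections from the annotations, or
#'   `"file"` to read a detection CSV.
#' @param detections_path detection CSV (required for `boxes = "file"`).
#' @param strategy,gcn_model,... passed to [new_tracker()].
#' @param scale_factor crop area ratio.
#' @return a [clip_annotation()] with predicted poses, confidences and
#'   track ids.
#' @export
track_clip <- function(clip, model, boxes = c("gt", "file"),
                       detections_path = NULL, strategy = "iou",
                       gcn_model = NULL, scale_factor = 2.2, ...) {
  boxes <- match.arg(boxes)
  ann <- clip$annotation
  det_file <- if (boxes == "file") {
    if (is.null(detections_path)) abort_ht("boxes='file' needs detections_path",
                                           "ht_schema_error")
    load_detections(detections_path)
  } else NULL
  conditional <- inherits(model, "condpose_model")
  tracker <- new_tracker(strategy = strategy, gcn_model = gcn_model, ...)
  pred_frames <- vector("list", length(ann$frames))
  for (k in seq_along(ann$frames)) {
    fr <- ann$frames[[k]]
    frame_boxes <- if (boxes == "gt") lapply(fr$hands, function(h) h$box)
    else lapply(det_file$for_frame(fr$frame_index), function(d) d$box)
    dets <- lapply(frame_boxes, function(b) {
      cr <- make_crop(clip$frames[[k]], b, scale_factor, model$cfg$input_size)
      list(crop = cr$image, geom = cr$geom, box = b)
    })
    results <- if (conditional) {
      priors <- lapply(tracker$tracks, function(tr) tr$heatmaps)
      priors <- priors[!vapply(priors, is.null, TRUE)]
      infer_frame(model, dets, priors)
    } else {
      lapply(dets, function(d) {
        out <- pose_forward(model, d$crop)
        list(heatmaps = out$heatmaps, prior_index = NA_integer_,
             confidence = mean_max_confidence(out$heatmaps))
      })
    }
    track_dets <- vector("list", length(dets))
    for (i in seq_along(dets)) {
      dec <- decode_heatmaps(results[[i]]$heatmaps, dets[[i]]$geom)
      pose <- decoded_to_pose(dec, dets[[i]]$box)
      emb <- if (strategy == "gcn")
        embed_pose(gcn_model, normalize_pose(pose, gcn_model$cfg$C)) else NULL
      track_dets[[i]] <- list(pose = pose, heatmaps = results[[i]]$heatmaps,
                              embedding = emb)
    }
    st <- step_tracker(tracker, track_dets)
    tracker <- st$state
    hands <- vector("list", length(dets))
    for (i in seq_along(dets)) {
      p <- track_dets[[i]]$pose
      p$track_id <- st$assignments[i]
      hands[[i]] <- p
    }
    pred_frames[[k]] <- list(frame_index = fr$frame_index, image = fr$image,
                             hands = hands)
  }
  clip_annotation(clip_id = ann$clip_id, fps = ann$fps, frames = pred_frames)
}

#' Run tracking and write the prediction file
#'
#' @param clip_dir clip directory with `frames/` and `annotation.json`.
#' @param model_path checkpoint path ([save_checkpoint()]).
#' @param out_path output prediction JSON path.
#' @param gcn_path optional GCN checkpoint (needed for `strategy = "gcn"`).
#' @inheritParams track_clip
#' @return the prediction [clip_annotation()], invisibly.
#' @export
run_track <- function(clip_dir, model_path, out_path, boxes = "gt",
                      detections_path = NULL, strategy = "iou",
                      gcn_path = NULL, ...) {
  clip <- read_clip_dir(clip_dir)
  model <- load_checkpoint(model_path)
  gcn_model <- if (!is.null(gcn_path)) load_checkpoint(gcn_path) else NULL
  pred <- track_clip(clip, model, boxes = boxes,
                     detections_path = detections_path,
                     strategy = strategy, gcn_model = gcn_model, ...)
  save_clip(pred, out_path)
  invisible(pred)
}

#' Evaluate prediction files against ground truth
#'
#' Writes `metrics.json` and a per-joint CSV table under `out_dir`.
#'
#' @param gt_paths,pred_paths clip JSON files, matched by clip_id.
#' @param out_dir output directory.
#' @param cfg an [eval_config()].
#' @return the metrics list, invisibly.
#' @export
run_evaluate <- function(gt_paths, pred_paths, out_dir, cfg = eval_config()) {
  gts <- lapply(gt_paths, load_clip)
  preds <- lapply(pred_paths, load_clip)
  gid <- vapply(gts, function(c) c$clip_id, "")
  pid <- vapply(preds, function(c) c$clip_id, "")
  missing <- setdiff(gid, pid)
  if (length(missing))
    abort_ht(paste0("prediction missing for clip: ", missing[1]), "ht_data_error")
  extra <- setdiff(pid, gid)
  if (length(extra))
    abort_ht(paste0("no ground truth for clip: ", extra[1]), "ht_data_error")
  det <- evaluate_map(preds, gts, cfg)
  trk <- evaluate_mota(preds, gts, cfg)
  metrics <- list(
    map = jsonlite::unbox(det$map), ap = det$ap,
    mota = jsonlite::unbox(trk$report$mota),
    mota_per_joint = trk$report$mota_per_joint,
    motp = jsonlite::unbox(trk$report$motp),
    precision = jsonlite::unbox(trk$report$precision),
    recall = jsonlite::unbox(trk$report$recall),
    f1 = jsonlite::unbox(trk$report$f1))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(metrics, null = "null", digits = NA, na = "null"),
             file.path(out_dir, "metrics.json"))
  tab <- data.frame(joint = HT_JOINT_NAMES, ap = det$ap,
                    mota = trk$report$mota_per_joint,
                    FN = trk$counts$FN, FP = trk$counts$FP,
                    IDSW = trk$counts$IDSW, G = trk$counts$G)
  utils::write.csv(tab, file.path(out_dir, "per_joint.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(list(detection = det, tracking = trk))
}

write_run_manifest <- function(out_dir, config, seed) {
  cfg_json <- jsonlite::toJSON(config, digits = NA, null = "null",
                               auto_unbox = TRUE, force = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    config_hash = jsonlite::unbox(unname(tools::md5sum(tmp))),
    seed = jsonlite::unbox(as.integer(seed)),
    package = jsonlite::unbox("handtrack"),
    package_version = jsonlite::unbox(as.character(utils::packageVersion("handtrack"))),
    config = config)
  unlink(tmp)
  writeLines(jsonlite::toJSON(manifest, digits = NA, null = "null",
                              auto_unbox = TRUE, force = TRUE),
             file.path(out_dir, "run_manifest.json"))
  invisible(manifest)
}

#' End-to-end demo on generated data
#'
#' Generates a small synthetic dataset, trains the frame-independent pose
#' network, finetunes the conditional model, tracks a held-out clip with
#' perfect boxes, and evaluates. All stages derive their seeds from `seed`,
#' so two runs with the same seed produce byte-identical prediction and
#' report files.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_clips dataset size (default 6).
#' @param posenet_epochs,cond_epochs training lengths for the demo.
#' @param strategy tracker strategy for the demo run.
#' @return list with paths and the evaluation metrics, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, n_clips = 6L, posenet_epochs = 2L,
                     cond_epochs = 2L, strategy = "iou") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- synth_config(n_frames = 8L, image_size = c(96L, 96L),
                       n_hands = c(1L, 3L), occlusion_prob = 0.15,
                       seed = derive_seed(seed, 21L))
  data_dir <- file.path(out_dir, "data")
  generate_dataset(n_clips, scfg, data_dir, overwrite = TRUE)
  train <- load_dataset_clips(data_dir, "train")
  val <- load_dataset_clips(data_dir, "val")
  if (length(val) == 0) val <- train[length(train)]

  pcfg <- posenet_config(epochs = posenet_epochs, seed = derive_seed(seed, 22L))
  samples <- do.call(c, lapply(train, function(cl)
    crop_samples_from_clip(cl$annotation, cl$frames, pcfg)))
  base <- train_posenet(samples, pcfg)
  ccfg <- cond_config(epochs = cond_epochs, seed = derive_seed(seed, 23L))
  cond <- train_condpose(train, base$model, ccfg)

  ckpt_dir <- file.path(out_dir, "checkpoints")
  dir.create(ckpt_dir, showWarnings = FALSE)
  save_checkpoint(base$model, file.path(ckpt_dir, "posenet.rds"))
  save_checkpoint(cond$model, file.path(ckpt_dir, "condpose.rds"))

  pred <- track_clip(val[[1]], cond$model, boxes = "gt", strategy = strategy)
  pred_path <- file.path(out_dir, "predictions.json")
  save_clip(pred, pred_path)
  gt_path <- file.path(out_dir, "gt.json")
  save_clip(val[[1]]$annotation, gt_path)
  metrics <- run_evaluate(gt_path, pred_path, file.path(out_dir, "report"))
  write_run_manifest(out_dir, list(
    seed = seed, n_clips = n_clips, synth = unclass(scfg),
    posenet_epochs = posenet_epochs, cond_epochs = cond_epochs,
    strategy = strategy), seed)
  invisible(list(prediction = pred_path, report = file.path(out_dir, "report"),
                 metrics = metrics))
}

#' Directional benchmark: conditional model vs frame-independent baseline
#'
#' Generates a seeded synthetic benchmark, trains the baseline pose network
#' on the training split, finetunes the conditional model from it, and
#' compares mean PCK at the configured threshold and MOTA (IoU matching,
#' perfect boxes) on the validation split. Conditional inference uses
#' ground-truth priors at `t - delta` (the training-time prior), isolating
#' the effect of temporal guidance from prior-selection noise.
#'
#' @param seed integer seed controlling data and both trainings.
#' @param n_clips benchmark size (default 30).
#' @param occlusion_prob occlusion rate of the benchmark (default 0.3).
#' @param posenet_epochs,cond_epochs training lengths.
#' @param delta temporal gap for the conditional model.
#' @return list with `pck_base`, `pck_cond`, `mota_base`, `mota_cond` and
#'   the underlying models.
#' @export
run_benchmark <- function(seed = 1L, n_clips = 30L, occlusion_prob = 0.3,
                          posenet_epochs = 6L, cond_epochs = 4L, delta = 3L) {
  scfg <- synth_config(n_frames = 8L, occlusion_prob = occlusion_prob,
                       seed = derive_seed(seed, 31L))
  counts <- with_rng_seed(derive_seed(seed, 32L), stratified_counts(n_clips))
  clips <- lapply(seq_len(n_clips), function(i) {
    ccfg <- scfg
    ccfg$seed <- derive_seed(scfg$seed, i)
    ccfg$n_hands <- counts[i]
    generate_clip(ccfg, clip_id = sprintf("clip%03d", i - 1L))
  })
  is_val <- seq_len(n_clips) %% 5L == 0L
  train <- clips[!is_val]
  val <- clips[is_val]

  pcfg <- posenet_config(epochs = posenet_epochs, seed = derive_seed(seed, 33L))
  samples <- do.call(c, lapply(train, function(cl)
    crop_samples_from_clip(cl$annotation, cl$frames, pcfg)))
  base <- train_posenet(samples, pcfg)
  ccfg <- cond_config(delta = delta, epochs = cond_epochs,
                      seed = derive_seed(seed, 34L))
  cond <- train_condpose(train, base$model, ccfg)

  ev <- eval_config()
  pck_base <- c(); pck_cond <- c()
  gt_anns <- list(); base_preds <- list(); cond_preds <- list()
  for (cl in val) {
    ann <- cl$annotation
    gt_tracks <- list()
    base_frames <- vector("list", length(ann$frames))
    cond_frames <- vector("list", length(ann$frames))
    base_trk <- new_tracker("iou")
    cond_trk <- new_tracker("iou")
    for (k in seq_along(ann$frames)) {
      fr <- ann$frames[[k]]
      bdets <- list(); cdets <- list()
      for (h in fr$hands) {
        cr <- make_crop(cl$frames[[k]], h$box, 2.2, pcfg$input_size)
        gt_hm <- encode_from_crop_xy(frame_to_crop(cr$geom, h$xy), h$state,
                                     pcfg$input_size, pcfg$heatmap_size,
                                     pcfg$sigma_hm)
        tid <- as.character(h$track_id)
        tr <- gt_tracks[[tid]] %||% new_track()
        prior <- select_prior(tr, fr$frame_index, ccfg$delta,
                              pcfg$heatmap_size, pcfg$J)
        gt_tracks[[tid]] <- track_store(tr, fr$frame_index, gt_hm)

        bout <- pose_forward(base$model, cr$image)
        cout <- condpose_forward(cond$model, cr$image, prior$heatmaps)
        bdec <- decode_heatmaps(bout$heatmaps, cr$geom)
        cdec <- decode_heatmaps(cout$heatmaps, cr$geom)
        bpose <- decoded_to_pose(bdec, h$box)
        cpose <- decoded_to_pose(cdec, h$box)
        pck_base <- c(pck_base, pck_match(bpose, h, ev)$pck)
        pck_cond <- c(pck_cond, pck_match(cpose, h, ev)$pck)
        bdets[[length(bdets) + 1L]] <- list(pose = bpose)
        cdets[[length(cdets) + 1L]] <- list(pose = cpose)
      }
      bs <- step_tracker(base_trk, bdets); base_trk <- bs$state
      cs <- step_tracker(cond_trk, cdets); cond_trk <- cs$state
      base_frames[[k]] <- list(
        frame_index = fr$frame_index, image = NULL,
        hands = lapply(seq_along(bdets), function(i) {
          p <- bdets[[i]]$pose; p$track_id <- bs$assignments[i]; p }))
      cond_frames[[k]] <- list(
        frame_index = fr$frame_index, image = NULL,
        hands = lapply(seq_along(cdets), function(i) {
          p <- cdets[[i]]$pose; p$track_id <- cs$assignments[i]; p }))
    }
    gt_anns[[length(gt_anns) + 1L]] <- ann
    base_preds[[length(base_preds) + 1L]] <-
      clip_annotation(ann$clip_id, ann$fps, base_frames)
    cond_preds[[length(cond_preds) + 1L]] <-
      clip_annotation(ann$clip_id, ann$fps, cond_frames)
  }
  mota_base <- evaluate_mota(base_preds, gt_anns, ev)$report$mota
  mota_cond <- evaluate_mota(cond_preds, gt_anns, ev)$report$mota
  list(pck_base = mean(pck_base, na.rm = TRUE),
       pck_cond = mean(pck_cond, na.rm = TRUE),
       mota_base = mota_base, mota_cond = mota_cond,
       base_model = base$model, cond_model = cond$model)
}
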