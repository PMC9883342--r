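# Detection and tracking evaluation: PCK, per-joint AP / mAP, and the
# multiple-object-tracking scores (MOTA, MOTP, precision, recall, F1) at
# joint level.
#
# A predicted joint is correct when it falls within sigma times the
# normalization length of the ground-truth box (default: the longer box
# side) of its annotated ground-truth joint. Poses are matched greedily by
# highest PCK; unmatched predictions count as false positives.

#' Evaluation configuration
#'
#' @param sigma normalized PCK distance threshold (default 0.2, roughly a
#'   thumb-phalanx length relative to the hand box).
#' @param normalization `"max_side"` (default) or `"diagonal"` of the
#'   ground-truth box.
#' @return object of class `eval_config`.
#' @export
eval_config <- function(sigma = 0.2, normalization = c("max_side", "diagonal")) {
  if (sigma <= 0) abort_ht("sigma must be positive", "ht_schema_error")
  structure(list(sigma = sigma, normalization = match.arg(normalization)),
            class = "eval_config")
}

pck_norm_length <- function(box, cfg) {
  if (cfg$normalization == "max_side") max(box_width(box), box_height(box))
  else box_diag(box)
}

#' Per-joint correctness and PCK of a predicted pose against ground truth
#'
#' @param pred,gt [hand_pose()] objects; `gt` must have at least one
#'   annotated joint.
#' @param cfg an [eval_config()].
#' @return list with `correct` (logical per joint; `NA` where the gt joint
#'   is unannotated), `dist` (pixel distances) and `pck` (correct fraction
#'   over annotated joints).
#' @export
pck_match <- function(pred, gt, cfg = eval_config()) {
  ann <- gt$state != "unannotated"
  thr <- cfg$sigma * pck_norm_length(gt$box, cfg)
  d <- sqrt(rowSums((pred$xy - gt$xy)^2))
  correct <- rep(NA, HT_J)
  correct[ann] <- d[ann] <= thr
  list(correct = correct, dist = d, threshold = thr,
       pck = if (any(ann)) sum(correct[ann]) / sum(ann) else NA_real_)
}

#' Match predicted poses to ground-truth poses within one frame
#'
#' Greedy one-to-one matching in descending PCK; pairs with PCK 0 are never
#' matched.
#'
#' @param preds,gts lists of [hand_pose()] for one frame.
#' @param cfg an [eval_config()].
#' @return list with `pairs` (two-column matrix of pred/gt indices),
#'   `unmatched_preds` and `unmatched_gts`.
#' @export
assign_poses <- function(preds, gts, cfg = eval_config()) {
  np <- length(preds); ng <- length(gts)
  P <- matrix(-Inf, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    v <- pck_match(preds[[i]], gts[[j]], cfg)$pck
    if (!is.na(v) && v > 0) P[i, j] <- v
  }
  m <- greedy_assign(t(P))   # columns = preds, rows = gts
  pairs <- cbind(pred = which(!is.na(m)), gt = m[!is.na(m)])
  list(pairs = pairs,
       unmatched_preds = setdiff(seq_len(np), pairs[, 1]),
       unmatched_gts = setdiff(seq_len(ng), pairs[, 2]))
}

clips_as_list <- function(x) {
  if (inherits(x, "clip_annotation")) list(x) else x
}

frame_map <- function(clip) {
  out <- list()
  for (fr in clip$frames) out[[as.character(fr$frame_index)]] <- fr
  out
}

#' Per-joint average precision and mAP over a dataset
#'
#' Predicted keypoints are ranked dataset-wide by confidence per joint; a
#' keypoint is a true positive when its pose was matched to a ground-truth
#' pose (highest-PCK matching) and the joint is correct at the configured
#' threshold. AP is the area under the interpolated precision-recall curve;
#' mAP is the mean over the 21 joints, on the 0-100 scale.
#'
#' @param preds,gts a [clip_annotation()] or list of them, aligned by
#'   clip_id.
#' @param cfg an [eval_config()].
#' @return list with `ap` (per joint, 0-100) and `map`.
#' @export
evaluate_map <- function(preds, gts, cfg = eval_config()) {
  preds <- clips_as_list(preds); gts <- clips_as_list(gts)
  gt_by_id <- stats::setNames(gts, vapply(gts, function(c) c$clip_id, ""))
  scores <- vector("list", HT_J)   # per joint: list of (conf, tp)
  npos <- integer(HT_J)
  for (pc in preds) {
    gc <- gt_by_id[[pc$clip_id]]
    if (is.null(gc)) abort_ht(paste0("no ground truth for clip ", pc$clip_id),
                              "ht_data_error")
    gmap <- frame_map(gc)
    for (fr in pc$frames) {
      gfr <- gmap[[as.character(fr$frame_index)]]
      gt_hands <- if (is.null(gfr)) list() else gfr$hands
      am <- assign_poses(fr$hands, gt_hands, cfg)
      matched_gt <- rep(NA_integer_, length(fr$hands))
      if (nrow(am$pairs)) matched_gt[am$pairs[, 1]] <- am$pairs[, 2]
      for (i in seq_along(fr$hands)) {
        h <- fr$hands[[i]]
        if (is.null(h$confidence))
          abort_ht("predictions must carry per-joint confidences", "ht_schema_error")
        gi <- matched_gt[i]
        res <- if (!is.na(gi)) pck_match(h, gt_hands[[gi]], cfg) else NULL
        for (j in seq_len(HT_J)) {
          if (h$state[j] == "unannotated") next
          if (!is.na(gi) && gt_hands[[gi]]$state[j] == "unannotated") next # ignored
          tp <- !is.na(gi) && isTRUE(res$correct[j])
          scores[[j]][[length(scores[[j]]) + 1L]] <- c(h$confidence[j], tp)
        }
      }
    }
  }
  for (gc in gts) for (fr in gc$frames) for (h in fr$hands) {
    ann <- h$state != "unannotated"
    npos <- npos + as.integer(ann)
  }
  ap <- numeric(HT_J)
  for (j in seq_len(HT_J)) {
    if (npos[j] == 0) { ap[j] <- NA_real_; next }
    if (length(scores[[j]]) == 0) { ap[j] <- 0; next }
    m <- do.call(rbind, scores[[j]])
    ord <- order(m[, 1], decreasing = TRUE)
    tp <- cumsum(m[ord, 2])
    fp <- cumsum(1 - m[ord, 2])
    recall <- tp / npos[j]
    prec <- tp / (tp + fp)
    prec_i <- rev(cummax(rev(prec)))          # interpolated envelope
    drec <- diff(c(0, recall))
    ap[j] <- sum(prec_i * drec) * 100
  }
  list(ap = ap, map = mean(ap, na.rm = TRUE))
}

#' MOTA, MOTP, precision, recall and F1 at joint level
#'
#' Frames are matched by highest PCK; per annotated ground-truth joint a
#' miss (FN) is counted when its pose is unmatched or the joint incorrect;
#' predicted joints of unmatched poses, and incorrect joints of matched
#' poses, count as false positives; an identity switch (IDSW) is counted for
#' every annotated joint of a ground-truth track whose matched predicted id
#' differs from the previously matched id. MOTA = 100 x (1 - (FN + FP +
#' IDSW) / G) per joint and pooled; MOTP = 100 x mean over correct matched
#' joints of (1 - d / threshold).
#'
#' @param preds,gts [clip_annotation()] or lists of them with track ids on
#'   both sides.
#' @param cfg an [eval_config()].
#' @return list with `report` (per-joint and total scores, 0-100 scale) and
#'   `counts` (per-joint FN/FP/IDSW/G).
#' @export
evaluate_mota <- function(preds, gts, cfg = eval_config()) {
  preds <- clips_as_list(preds); gts <- clips_as_list(gts)
  gt_by_id <- stats::setNames(gts, vapply(gts, function(c) c$clip_id, ""))
  FN <- FP <- IDSW <- G <- integer(HT_J)
  motp_sum <- 0; motp_n <- 0L
  for (pc in preds) {
    gc <- gt_by_id[[pc$clip_id]]
    if (is.null(gc)) abort_ht(paste0("no ground truth for clip ", pc$clip_id),
                              "ht_data_error")
    pmap <- frame_map(pc)
    last_pred_id <- list()   # gt track id -> predicted id at last match
    for (gfr in gc$frames) {
      pfr <- pmap[[as.character(gfr$frame_index)]]
      pred_hands <- if (is.null(pfr)) list() else pfr$hands
      gt_hands <- gfr$hands
      for (h in gt_hands) {
        if (is.null(h$track_id)) abort_ht("ground truth must carry track ids",
                                          "ht_schema_error")
      }
      am <- assign_poses(pred_hands, gt_hands, cfg)
      matched_pred_of_gt <- rep(NA_integer_, length(gt_hands))
      if (nrow(am$pairs)) matched_pred_of_gt[am$pairs[, 2]] <- am$pairs[, 1]
      for (gi in seq_along(gt_hands)) {
        gh <- gt_hands[[gi]]
        ann <- gh$state != "unannotated"
        G <- G + as.integer(ann)
        pi <- matched_pred_of_gt[gi]
        if (is.na(pi)) {
          FN <- FN + as.integer(ann)
          next
        }
        ph <- pred_hands[[pi]]
        if (is.null(ph$track_id)) abort_ht("predictions must carry track ids",
                                           "ht_schema_error")
        res <- pck_match(ph, gh, cfg)
        pj_pred <- ph$state != "unannotated"
        for (j in which(ann)) {
          if (!pj_pred[j] || !isTRUE(res$correct[j])) {
            FN[j] <- FN[j] + 1L
            if (pj_pred[j]) FP[j] <- FP[j] + 1L   # incorrect hypothesis
          } else {
            motp_sum <- motp_sum + (1 - res$dist[j] / res$threshold)
            motp_n <- motp_n + 1L
          }
        }
        key <- as.character(gh$track_id)
        prev <- last_pred_id[[key]]
        if (!is.null(prev) && prev != ph$track_id) {
          IDSW <- IDSW + as.integer(ann)
        }
        last_pred_id[[key]] <- ph$track_id
      }
      for (pi in am$unmatched_preds) {
        ph <- pred_hands[[pi]]
        FP <- FP + as.integer(ph$state != "unannotated")
      }
    }
  }
  TPj <- G - FN
  mota_j <- ifelse(G > 0, 100 * (1 - (FN + FP + IDSW) / G), NA_real_)
  Gt <- sum(G)
  report <- list(
    mota_per_joint = mota_j,
    mota = 100 * (1 - (sum(FN) + sum(FP) + sum(IDSW)) / Gt),
    motp = if (motp_n > 0) 100 * motp_sum / motp_n else NA_real_,
    precision = if (sum(TPj) + sum(FP) > 0) 100 * sum(TPj) / (sum(TPj) + sum(FP)) else NA_real_,
    recall = if (Gt > 0) 100 * sum(TPj) / Gt else NA_real_)
  report$f1 <- if (!is.na(report$precision) && !is.na(report$recall) &&
                   report$precision + report$recall > 0)
    2 * report$precision * report$recall / (report$precision + report$recall)
  else NA_real_
  counts <- data.frame(joint = HT_JOINT_NAMES, FN = FN, FP = FP, IDSW = IDSW, G = G)
  list(report = report, counts = counts)
}
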