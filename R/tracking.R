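# Detect-then-track data association. Detections at frame t are matched to
# live tracks from frame t-1 by a similarity function (bounding-box IoU,
# negative mean keypoint distance, or negative contrastive embedding
# distance), with greedy one-to-one assignment in descending similarity.
# Unmatched detections open new ids; unmatched tracks age out.

#' Intersection over union of two boxes
#' @param a,b bounding boxes (x0, y0, x1, y1), half-open.
#' @return overlap ratio in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ix <- min(a[3], b[3]) - max(a[1], b[1])
  iy <- min(a[4], b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (box_area(a) + box_area(b) - inter)
}

#' Mean Euclidean distance between two poses' shared annotated joints
#'
#' @param a,b [hand_pose()] objects.
#' @return mean L2 distance in pixels over joints annotated in both poses,
#'   or `NA` (treated as a non-match) if they share none.
#' @export
mean_keypoint_distance <- function(a, b) {
  shared <- a$state != "unannotated" & b$state != "unannotated"
  if (!any(shared)) return(NA_real_)
  d <- sqrt(rowSums((a$xy[shared, , drop = FALSE] - b$xy[shared, , drop = FALSE])^2))
  mean(d)
}

#' Create a tracker
#'
#' @param strategy `"iou"`, `"l2"` or `"gcn"`.
#' @param iou_threshold minimum IoU for a match (default 0.2).
#' @param l2_threshold maximum mean keypoint distance for a match, as a
#'   fraction of the detection's box diagonal (default 0.5).
#' @param embed_threshold maximum embedding distance for a GCN match, in the
#'   loss geometry (default: an L2 distance of half the embedder's margin).
#' @param max_age frames a track survives unmatched (default 1: only t-1
#'   tracks are match candidates).
#' @param gcn_model trained `gcn_model`, required for `strategy = "gcn"`.
#' @param assignment `"greedy"` (default) or `"optimal"` (exhaustive
#'   min-cost assignment, small frames only).
#' @return object of class `tracker_state`.
#' @export
new_tracker <- function(strategy = c("iou", "l2", "gcn"), iou_threshold = 0.2,
                        l2_threshold = 0.5, embed_threshold = NULL,
                        max_age = 1L, gcn_model = NULL,
                        assignment = c("greedy", "optimal")) {
  strategy <- match.arg(strategy)
  assignment <- match.arg(assignment)
  if (strategy == "gcn") {
    if (is.null(gcn_model)) abort_ht("strategy 'gcn' needs a gcn_model", "ht_schema_error")
    if (is.null(embed_threshold)) embed_threshold <- pair_threshold(gcn_model$cfg)
  }
  structure(list(tracks = list(), next_id = 0L, strategy = strategy,
                 iou_threshold = iou_threshold, l2_threshold = l2_threshold,
                 embed_threshold = embed_threshold, max_age = as.integer(max_age),
                 gcn_model = gcn_model, assignment = assignment),
            class = "tracker_state")
}

# similarity matrix tracks x detections; -Inf marks below-threshold pairs
similarity_matrix <- function(state, dets) {
  nt <- length(state$tracks); nd <- length(dets)
  S <- matrix(-Inf, nt, nd)
  for (i in seq_len(nt)) {
    tr <- state$tracks[[i]]
    for (j in seq_len(nd)) {
      d <- dets[[j]]
      if (state$strategy == "iou") {
        v <- iou(tr$pose$box, d$pose$box)
        if (v >= state$iou_threshold) S[i, j] <- v
      } else if (state$strategy == "l2") {
        v <- mean_keypoint_distance(tr$pose, d$pose)
        lim <- state$l2_threshold * box_diag(d$pose$box)
        if (!is.na(v) && v <= lim) S[i, j] <- -v
      } else {
        e1 <- tr$embedding %||% embed_pose(state$gcn_model,
                                           normalize_pose(tr$pose, state$gcn_model$cfg$C))
        e2 <- d$embedding %||% embed_pose(state$gcn_model,
                                          normalize_pose(d$pose, state$gcn_model$cfg$C))
        v <- embedding_distance(e1, e2, state$gcn_model$cfg$loss_mode)
        if (v <= state$embed_threshold) S[i, j] <- -v
      }
    }
  }
  S
}

#' Greedy descending-similarity one-to-one assignment
#'
#' @param S similarity matrix (rows = tracks, columns = detections); `-Inf`
#'   entries are never matched. Ties resolve to the lowest row, then column.
#' @return integer vector over columns: matched row index or `NA`.
#' @export
greedy_assign <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  match_col <- rep(NA_integer_, nc)
  if (nr == 0 || nc == 0) return(match_col)
  used_r <- rep(FALSE, nr); used_c <- rep(FALSE, nc)
  repeat {
    best <- -Inf; bi <- 0L; bj <- 0L
    for (j in seq_len(nc)) {
      if (used_c[j]) next
      for (i in seq_len(nr)) {
        if (used_r[i]) next
        if (S[i, j] > best) { best <- S[i, j]; bi <- i; bj <- j }
      }
    }
    if (!is.finite(best)) break
    match_col[bj] <- bi
    used_r[bi] <- TRUE; used_c[bj] <- TRUE
  }
  match_col
}

# Exhaustive optimal assignment (maximum total similarity over one-to-one
# matchings); exponential, intended for small frames.
optimal_assign <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  match_col <- rep(NA_integer_, nc)
  if (nr == 0 || nc == 0) return(match_col)
  if (min(nr, nc) > 8L) abort_ht("optimal assignment limited to 8 objects", "ht_schema_error")
  cols <- seq_len(nc)
  best_val <- -Inf; best_match <- match_col
  assign_rec <- function(i, used_c, cur, matches) {
    if (i > nr) {
      if (cur > best_val) { best_val <<- cur; best_match <<- matches }
      return(invisible())
    }
    assign_rec(i + 1L, used_c, cur, matches)  # row i unmatched
    for (j in cols) {
      if (used_c[j] || !is.finite(S[i, j])) next
      used_c[j] <- TRUE
      m2 <- matches; m2[j] <- i
      assign_rec(i + 1L, used_c, cur + S[i, j], m2)
      used_c[j] <- FALSE
    }
  }
  assign_rec(1L, rep(FALSE, nc), 0, match_col)
  best_match
}

#' Advance the tracker by one frame
#'
#' @param state a `tracker_state`.
#' @param detections list of detections, each a list with `pose` (a
#'   [hand_pose()], predicted joints and box) and optionally `heatmaps` (the
#'   fused stack stored for future priors) and `embedding`.
#' @return list with `state` (updated) and `assignments` (integer track id
#'   per detection).
#' @export
step_tracker <- function(state, detections) {
  S <- similarity_matrix(state, detections)
  m <- if (state$assignment == "optimal") optimal_assign(S) else greedy_assign(S)
  ids <- integer(length(detections))
  matched_tracks <- rep(FALSE, length(state$tracks))
  new_tracks <- list()
  for (j in seq_along(detections)) {
    d <- detections[[j]]
    if (!is.na(m[j])) {
      tr <- state$tracks[[m[j]]]
      matched_tracks[m[j]] <- TRUE
      tr$pose <- d$pose
      tr$heatmaps <- d$heatmaps %||% tr$heatmaps
      tr$embedding <- d$embedding
      tr$age <- 0L
      ids[j] <- tr$id
      new_tracks[[length(new_tracks) + 1L]] <- tr
    } else {
      tr <- list(id = state$next_id, pose = d$pose, heatmaps = d$heatmaps,
                 embedding = d$embedding, age = 0L)
      state$next_id <- state$next_id + 1L
      ids[j] <- tr$id
      new_tracks[[length(new_tracks) + 1L]] <- tr
    }
  }
  for (i in seq_along(state$tracks)) {
    if (matched_tracks[i]) next
    tr <- state$tracks[[i]]
    tr$age <- tr$age + 1L
    if (tr$age < state$max_age) new_tracks[[length(new_tracks) + 1L]] <- tr
  }
  state$tracks <- new_tracks
  list(state = state, assignments = ids)
}
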