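# Domain types: keypoints, hand poses, clip annotations.
#
# A hand carries exactly 21 joints in a fixed order: index 1 = wrist,
# 2-5 thumb (base to tip), 6-9 index, 10-13 middle, 14-17 ring, 18-21 pinky.
# Coordinates are 0-based pixel centers (x right, y down); bounding boxes are
# half-open [x0, x1) x [y0, y1).

#' Number of joints in the hand model
#' @export
HT_J <- 21L

#' Joint names in canonical order
#' @export
HT_JOINT_NAMES <- c(
  "wrist",
  paste0("thumb", 1:4), paste0("index", 1:4), paste0("middle", 1:4),
  paste0("ring", 1:4), paste0("pinky", 1:4))

#' Skeleton edges (bones) as a 2-column matrix of joint indices
#'
#' Each finger is a chain of four joints rooted at the wrist.
#' @export
HT_SKELETON <- {
  e <- rbind(cbind(1L, c(2L, 6L, 10L, 14L, 18L)))
  for (f in 0:4) {
    b <- 2L + 4L * f
    e <- rbind(e, cbind(b + 0:2, b + 1:3))
  }
  e
}

HT_STATES <- c("visible", "occluded", "unannotated")

#' Construct a bounding box
#'
#' @param x0,y0,x1,y1 box edges in pixels; half-open, `x1 > x0`, `y1 > y0`.
#' @return numeric vector of class `ht_box`.
#' @export
ht_box <- function(x0, y0, x1, y1) {
  b <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  validate_box(b)
  structure(b, class = "ht_box")
}

validate_box <- function(b, what = "box") {
  if (length(b) != 4L || !is.numeric(b) || any(!is.finite(b)))
    abort_ht(sprintf("%s must be 4 finite numbers (x0, y0, x1, y1)", what), "ht_schema_error")
  if (b[[3]] <= b[[1]] || b[[4]] <= b[[2]])
    abort_ht(sprintf("%s is degenerate: requires x1 > x0 and y1 > y0", what), "ht_schema_error")
  invisible(b)
}

box_width <- function(b) b[[3]] - b[[1]]
box_height <- function(b) b[[4]] - b[[2]]
box_center <- function(b) c((b[[1]] + b[[3]]) / 2, (b[[2]] + b[[4]]) / 2)
box_area <- function(b) box_width(b) * box_height(b)
box_diag <- function(b) sqrt(box_width(b)^2 + box_height(b)^2)

#' Construct a hand pose
#'
#' @param xy 21 x 2 numeric matrix of joint coordinates in frame pixels.
#' @param state character vector of length 21; each of `"visible"`,
#'   `"occluded"` or `"unannotated"`. Coordinates of unannotated joints are
#'   ignored by every loss and metric.
#' @param handedness `"left"` or `"right"`.
#' @param box bounding box (`ht_box` or length-4 numeric).
#' @param track_id non-negative integer track id, or `NULL` when unset.
#' @param confidence per-joint confidence in `[0, 1]` for predicted poses, or
#'   `NULL` for ground truth.
#' @return object of class `hand_pose`.
#' @export
hand_pose <- function(xy, state, handedness, box, track_id = NULL, confidence = NULL) {
  p <- structure(list(xy = xy, state = state, handedness = handedness,
                      box = as.numeric(box), track_id = track_id,
                      confidence = confidence),
                 class = "hand_pose")
  validate_pose(p)
  p
}

validate_pose <- function(p, what = "hand") {
  if (!is.matrix(p$xy) || nrow(p$xy) != HT_J || ncol(p$xy) != 2L)
    abort_ht(sprintf("%s$keypoints: expected %d keypoints as a %dx2 matrix, got %s",
                     what, HT_J, HT_J,
                     if (is.matrix(p$xy)) paste0(nrow(p$xy), "x", ncol(p$xy)) else "non-matrix"),
             "ht_schema_error")
  if (length(p$state) != HT_J || !all(p$state %in% HT_STATES))
    abort_ht(sprintf("%s$state: expected %d values among {%s}", what, HT_J,
                     paste(HT_STATES, collapse = ", ")), "ht_schema_error")
  ann <- p$state != "unannotated"
  if (any(!is.finite(p$xy[ann, ])))
    abort_ht(sprintf("%s$keypoints: non-finite coordinates on annotated joints", what),
             "ht_schema_error")
  if (!p$handedness %in% c("left", "right"))
    abort_ht(sprintf("%s$handedness: must be 'left' or 'right'", what), "ht_schema_error")
  validate_box(p$box, paste0(what, "$box"))
  if (!is.null(p$track_id) &&
      !(is_count(p$track_id)))
    abort_ht(sprintf("%s$track_id: must be a non-negative integer or unset", what),
             "ht_schema_error")
  if (!is.null(p$confidence) &&
      (length(p$confidence) != HT_J || any(!is.finite(p$confidence)) ||
       any(p$confidence < 0 | p$confidence > 1)))
    abort_ht(sprintf("%s$confidence: must be %d values in [0, 1]", what, HT_J),
             "ht_schema_error")
  invisible(p)
}

#' Construct a clip annotation
#'
#' A clip is an ordered sequence of frames; each frame holds the (possibly
#' empty) list of hand poses present in it plus an optional image path
#' relative to the annotation file.
#'
#' @param clip_id character clip identifier.
#' @param fps frames per second.
#' @param frames list of frames, each a list with `frame_index` (integer),
#'   `image` (relative path or `NULL`) and `hands` (list of [hand_pose()]).
#' @param extra named list of unknown top-level fields preserved on round-trip.
#' @return object of class `clip_annotation`.
#' @export
clip_annotation <- function(clip_id, fps, frames, extra = list()) {
  clip <- structure(list(clip_id = clip_id, fps = fps, frames = frames,
                         extra = extra),
                    class = "clip_annotation")
  validate_clip(clip)
  clip
}

validate_clip <- function(clip) {
  if (!is.character(clip$clip_id) || length(clip$clip_id) != 1L)
    abort_ht("clip_id must be a single string", "ht_schema_error")
  if (!is.numeric(clip$fps) || length(clip$fps) != 1L || clip$fps <= 0)
    abort_ht("fps must be a positive number", "ht_schema_error")
  idx <- vapply(clip$frames, function(f) as.numeric(f$frame_index), 0)
  if (length(idx) > 1L && any(diff(idx) <= 0))
    abort_ht("frames: frame_index must be strictly increasing", "ht_schema_error")
  for (f in clip$frames) {
    ids <- unlist(lapply(f$hands, function(h) h$track_id))
    if (anyDuplicated(ids))
      abort_ht(sprintf("frame %d: duplicate track_id %s within one frame",
                       f$frame_index, ids[duplicated(ids)][1]), "ht_schema_error")
    for (k in seq_along(f$hands))
      validate_pose(f$hands[[k]], sprintf("frame %d hand %d", f$frame_index, k))
  }
  invisible(clip)
}

#' @export
print.clip_annotation <- function(x, ...) {
  nh <- sum(vapply(x$frames, function(f) length(f$hands), 0L))
  cat(sprintf("<clip_annotation '%s'> %d frames, %d hand annotations, %.3g fps\n",
              x$clip_id, length(x$frames), nh, x$fps))
  invisible(x)
}

#' @export
print.hand_pose <- function(x, ...) {
  cat(sprintf("<hand_pose> %s, track %s, %d/%d annotated joints\n",
              x$handedness, x$track_id %||% "unset", sum(x$state != "unannotated"), HT_J))
  invisible(x)
}
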