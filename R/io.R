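# Annotation / prediction JSON dialect.
#
# One JSON object per clip:
#   { "clip_id": str, "fps": num, "format": "handtrack-clip-v1",
#     "frames": [ { "frame_index": int, "image": str|null, "hands": [ ... ] } ] }
# each hand:
#   { "box": [x0,y0,x1,y1], "confidence": [21]|null, "handedness": "left"|"right",
#     "keypoints": [[x,y] x 21], "state": ["visible"|"occluded"|"unannotated" x 21],
#     "track_id": int|null }
# Keys are written sorted, so identical clips serialize to identical bytes.
# Unknown fields at clip, frame and hand level are preserved on round-trip.

CLIP_FORMAT <- "handtrack-clip-v1"
CLIP_KEYS <- c("clip_id", "format", "fps", "frames")
FRAME_KEYS <- c("frame_index", "hands", "image")
HAND_KEYS <- c("box", "confidence", "handedness", "keypoints", "state", "track_id")

#' Load a clip annotation / prediction file
#'
#' @param path path to a clip JSON file.
#' @return a validated [clip_annotation()].
#' @export
load_clip <- function(path) {
  if (!file.exists(path)) abort_ht(paste0("no such file: ", path), "ht_io_error")
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort_ht(paste0("JSON parse failure in ", path,
                                                      ": ", conditionMessage(e)),
                                               "ht_parse_error"))
  for (key in c("clip_id", "fps", "frames")) {
    if (is.null(raw[[key]]))
      abort_ht(paste0("missing required field: ", key), "ht_schema_error")
  }
  frames <- lapply(raw$frames, parse_frame)
  extra <- raw[setdiff(names(raw), CLIP_KEYS)]
  clip_annotation(clip_id = as.character(raw$clip_id), fps = as.numeric(raw$fps),
                  frames = frames, extra = extra)
}

parse_frame <- function(fr) {
  if (is.null(fr$frame_index))
    abort_ht("missing required field: frame_index", "ht_schema_error")
  hands <- lapply(fr$hands %||% list(), parse_hand)
  out <- list(frame_index = as.integer(fr$frame_index),
              image = if (is.null(fr$image)) NULL else as.character(fr$image),
              hands = hands)
  ex <- fr[setdiff(names(fr), FRAME_KEYS)]
  if (length(ex)) out$extra <- ex
  out
}

parse_hand <- function(h) {
  kp <- h$keypoints
  if (is.null(kp) || length(kp) != HT_J)
    abort_ht(sprintf("hand$keypoints: expected %d keypoints, got %d",
                     HT_J, length(kp)), "ht_schema_error")
  xy <- t(vapply(kp, function(p) as.numeric(unlist(p))[1:2], numeric(2)))
  state <- as.character(unlist(h$state))
  conf <- if (is.null(h$confidence) || length(h$confidence) == 0) NULL else
    as.numeric(unlist(h$confidence))
  tid <- if (is.null(h$track_id)) NULL else as.integer(h$track_id)
  pose <- hand_pose(xy = xy, state = state,
                    handedness = as.character(h$handedness),
                    box = as.numeric(unlist(h$box)),
                    track_id = tid, confidence = conf)
  ex <- h[setdiff(names(h), HAND_KEYS)]
  if (length(ex)) pose$extra <- ex
  pose
}

#' Save a clip annotation / prediction file
#'
#' Serialization is canonical (sorted keys, fixed number formatting):
#' identical clips produce identical bytes.
#'
#' @param clip a [clip_annotation()].
#' @param path output path.
#' @export
save_clip <- function(clip, path) {
  validate_clip(clip)
  body <- list(
    clip_id = jsonlite::unbox(clip$clip_id),
    format = jsonlite::unbox(CLIP_FORMAT),
    fps = jsonlite::unbox(clip$fps),
    frames = lapply(clip$frames, serialize_frame))
  body <- c(body, clip$extra %||% list())
  body <- body[order(names(body))]
  txt <- jsonlite::toJSON(body, null = "null", digits = NA, pretty = FALSE,
                          auto_unbox = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

serialize_frame <- function(fr) {
  out <- list(frame_index = jsonlite::unbox(as.integer(fr$frame_index)),
              hands = lapply(fr$hands, serialize_hand),
              image = if (is.null(fr$image)) NULL else jsonlite::unbox(fr$image))
  out <- c(out, fr$extra %||% list())
  out[order(names(out))]
}

serialize_hand <- function(h) {
  out <- list(
    box = as.numeric(h$box),
    confidence = if (is.null(h$confidence)) NULL else as.numeric(h$confidence),
    handedness = jsonlite::unbox(h$handedness),
    keypoints = lapply(seq_len(HT_J), function(j) as.numeric(h$xy[j, ])),
    state = as.list(h$state),
    track_id = if (is.null(h$track_id)) NULL else jsonlite::unbox(as.integer(h$track_id)))
  out <- c(out, h$extra %||% list())
  out[order(names(out))]
}

#' Load per-frame detections
#'
#' Reads a CSV with columns `frame_index, x0, y0, x1, y1[, score]`, one row
#' per detected box.
#'
#' @param path detection CSV path.
#' @return object of class `ht_detections`: a list with `$table` (the parsed
#'   data frame) and `$for_frame(i)` returning the (possibly empty) list of
#'   boxes for frame `i`, each with optional `$score`.
#' @export
load_detections <- function(path) {
  if (!file.exists(path)) abort_ht(paste0("no such file: ", path), "ht_io_error")
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) abort_ht(paste0("malformed detection file: ",
                                                      conditionMessage(e)), "ht_parse_error"))
  need <- c("frame_index", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(tab)))
    abort_ht(paste0("detection file must have columns ",
                    paste(need, collapse = ", ")), "ht_schema_error")
  for (i in seq_len(nrow(tab))) {
    validate_box(as.numeric(tab[i, c("x0", "y0", "x1", "y1")]),
                 sprintf("detection row %d", i))
  }
  structure(list(
    table = tab,
    for_frame = function(i) {
      rows <- which(tab$frame_index == i)
      lapply(rows, function(r) {
        d <- list(box = as.numeric(tab[r, c("x0", "y0", "x1", "y1")]))
        if ("score" %in% names(tab)) d$score <- tab$score[r]
        d
      })
    }), class = "ht_detections")
}

#' Write per-frame detections
#'
#' Inverse of [load_detections()]; mainly used to derive detection files from
#' ground-truth boxes.
#'
#' @param rows data frame with columns `frame_index, x0, y0, x1, y1[, score]`.
#' @param path output CSV path.
#' @export
save_detections <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
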