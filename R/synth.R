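# Synthetic multi-instance articulated-hand clips with exact ground truth.
#
# Each hand is a planar kinematic skeleton: a wrist root plus five chains of
# four joints (21 keypoints total). Per-finger flexion angles evolve as
# bounded random walks; a global similarity transform (position, orientation)
# moves the whole hand between frames. Hands are rendered as filled capsules
# in a glove color over a smoothly textured background; opaque "instrument"
# rectangles sweep across hands to create occlusion episodes. Joints under an
# occluder or a hand drawn above keep their true coordinates with state
# "occluded"; joints off the image become "unannotated".

# Hands-per-frame distribution emulating a busy multi-person scene:
# mean ~2.9, median 3, maximum 7.
HANDS_PROBS <- c(0.17, 0.26, 0.29, 0.14, 0.08, 0.04, 0.02)

#' Synthetic clip configuration
#'
#' @param n_frames number of frames per clip.
#' @param image_size frame size in pixels as `c(H, W)`.
#' @param n_hands fixed hand count, a range `c(min, max)`, or `NULL` to draw
#'   from the default hands-per-frame distribution (mean about 2.9, max 7).
#' @param motion_speed wrist translation speed in pixels/frame.
#' @param flexion_rate standard deviation of the per-frame flexion random
#'   walk, in radians/frame.
#' @param occlusion_prob target fraction of (hand, frame) pairs under an
#'   instrument occluder.
#' @param glove_palette list of RGB triplets in `[0, 1]` used as glove colors.
#' @param seed integer seed; the clip is a deterministic function of the
#'   config including the seed.
#' @param max_hands cap on the number of hands (default 7).
#' @param hand_scale range of the wrist-to-knuckle distance as a fraction of
#'   the smaller image side.
#' @param keep_masks if `TRUE`, [generate_clip()] also returns per-hand
#'   silhouette and occluder masks (used by rendering diagnostics).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_frames = 10L, image_size = c(128L, 128L),
                         n_hands = NULL, motion_speed = 2, flexion_rate = 0.12,
                         occlusion_prob = 0.1,
                         glove_palette = list(c(0.93, 0.89, 0.80),
                                              c(0.24, 0.55, 0.38),
                                              c(0.45, 0.58, 0.72),
                                              c(0.88, 0.86, 0.92)),
                         seed = 1L, max_hands = 7L,
                         hand_scale = c(0.17, 0.23), keep_masks = FALSE) {
  if (occlusion_prob < 0 || occlusion_prob > 1)
    abort_ht("occlusion_prob must lie in [0, 1]", "ht_schema_error")
  if (!is.null(n_hands) && max(n_hands) > max_hands)
    abort_ht("n_hands exceeds max_hands", "ht_schema_error")
  if (min(image_size) < 48L)
    abort_ht("image_size too small for the skeleton extent", "ht_schema_error")
  structure(list(n_frames = as.integer(n_frames), image_size = as.integer(image_size),
                 n_hands = n_hands, motion_speed = motion_speed,
                 flexion_rate = flexion_rate, occlusion_prob = occlusion_prob,
                 glove_palette = glove_palette, seed = as.integer(seed),
                 max_hands = as.integer(max_hands), hand_scale = hand_scale,
                 keep_masks = isTRUE(keep_masks)),
            class = "synth_config")
}

# Per-hand anatomy (sampled once per hand) ------------------------------------

sample_hand_anatomy <- function(unit, handedness) {
  side <- if (handedness == "right") 1 else -1
  spread <- c(-1.05, -0.38, 0, 0.30, 0.62) * side + stats::rnorm(5, 0, 0.06)
  mcp_dist <- c(0.45, 0.98, 1.00, 0.97, 0.88) * unit * stats::runif(5, 0.95, 1.05)
  seg <- rbind(c(0.50, 0.32, 0.25),   # thumb
               c(0.45, 0.28, 0.20),   # index
               c(0.50, 0.30, 0.22),   # middle
               c(0.46, 0.28, 0.20),   # ring
               c(0.34, 0.22, 0.17)) * unit * stats::runif(1, 0.92, 1.08)
  curl_factor <- c(0.30, rep(0.5, 4))
  list(unit = unit, side = side, spread = spread, mcp_dist = mcp_dist,
       seg = seg, curl_factor = curl_factor,
       finger_shade = stats::runif(5, 0.82, 1.12),
       palm_shade = stats::runif(1, 0.9, 1.05))
}

# 21 joint positions for one hand at state (position w, orientation theta,
# flexion phi per finger).
hand_joints <- function(an, w, theta, phi) {
  xy <- matrix(0, HT_J, 2)
  xy[1, ] <- w
  for (f in 1:5) {
    a0 <- theta + an$spread[f]
    base <- w + an$mcp_dist[f] * c(cos(a0), sin(a0))
    j <- 2L + 4L * (f - 1L)
    xy[j, ] <- base
    p <- base
    for (k in 1:3) {
      ang <- a0 + an$side * phi[f] * an$curl_factor[f] * k
      p <- p + an$seg[f, k] * c(cos(ang), sin(ang))
      xy[j + k, ] <- p
    }
  }
  xy
}

# Rasterization ---------------------------------------------------------------

# Paint a filled capsule (segment p-q with radius r) into img (H x W x 3),
# returning the updated image and the coverage mask.
paint_capsule <- function(img, mask, p, q, r, col) {
  d <- dim(img)
  x0 <- max(1L, floor(min(p[1], q[1]) - r)); x1 <- min(d[2], ceiling(max(p[1], q[1]) + r) + 1L)
  y0 <- max(1L, floor(min(p[2], q[2]) - r)); y1 <- min(d[1], ceiling(max(p[2], q[2]) + r) + 1L)
  if (x0 > x1 || y0 > y1) return(list(img = img, mask = mask))
  xs <- (x0:x1) - 1; ys <- (y0:y1) - 1
  gx <- outer(rep(1, length(ys)), xs)
  gy <- outer(ys, rep(1, length(xs)))
  v <- q - p
  L2 <- sum(v * v)
  if (L2 < 1e-12) {
    dx <- gx - p[1]; dy <- gy - p[2]
  } else {
    t <- ((gx - p[1]) * v[1] + (gy - p[2]) * v[2]) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- gx - (p[1] + t * v[1]); dy <- gy - (p[2] + t * v[2])
  }
  dist2 <- dx * dx + dy * dy
  hit <- dist2 <= r * r
  if (!any(hit)) return(list(img = img, mask = mask))
  shade <- 1 - 0.25 * dist2 / (r * r)
  for (ch in 1:3) {
    plane <- img[y0:y1, x0:x1, ch]
    plane[hit] <- pmin(1, pmax(0, col[ch] * shade[hit]))
    img[y0:y1, x0:x1, ch] <- plane
  }
  sub <- mask[y0:y1, x0:x1]
  sub[hit] <- TRUE
  mask[y0:y1, x0:x1] <- sub
  list(img = img, mask = mask)
}

render_hand <- function(img, an, xy, col) {
  u <- an$unit
  mask <- matrix(FALSE, dim(img)[1], dim(img)[2])
  # palm: wrist to each knuckle, plus the knuckle arc
  pc <- col * an$palm_shade
  for (f in 1:5) {
    r <- if (f == 1) 0.13 * u else 0.15 * u
    z <- paint_capsule(img, mask, xy[1, ], xy[2L + 4L * (f - 1L), ], r, pc)
    img <- z$img; mask <- z$mask
  }
  for (f in 2:4) {
    z <- paint_capsule(img, mask, xy[2L + 4L * (f - 1L), ], xy[2L + 4L * f, ], 0.13 * u, pc)
    img <- z$img; mask <- z$mask
  }
  radii <- c(0.095, 0.085, 0.075) * u
  for (f in 1:5) {
    j <- 2L + 4L * (f - 1L)
    fc <- col * an$finger_shade[f]
    for (k in 1:3) {
      z <- paint_capsule(img, mask, xy[j + k - 1L, ], xy[j + k, ],
                         radii[k] * (if (f == 1) 1.25 else 1), fc)
      img <- z$img; mask <- z$mask
    }
  }
  list(img = img, mask = mask)
}

render_background <- function(H, W) {
  base <- stats::runif(3, 0.25, 0.45)
  coarse <- array(stats::rnorm(8 * 8 * 3, 0, 1), c(8, 8, 3))
  xs <- seq(0.5, 7.5 - 1e-9, length.out = W) - 0.5
  ys <- seq(0.5, 7.5 - 1e-9, length.out = H) - 0.5
  tex <- bilinear_sample(coarse, xs, ys)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- pmin(1, pmax(0, base[ch] + 0.05 * tex[, , ch]))
  img
}

#' Generate one synthetic clip
#'
#' @param config a [synth_config()].
#' @param clip_id clip identifier stored in the annotation.
#' @return list with `frames` (list of H x W x 3 arrays), `annotation` (a
#'   [clip_annotation()] with exact joint positions, per-joint states, tight
#'   boxes and persistent track ids) and, when `config$keep_masks`, `masks`.
#' @export
generate_clip <- function(config, clip_id = "clip") {
  stopifnot(inherits(config, "synth_config"))
  with_rng_seed(config$seed, generate_clip_impl(config, clip_id))
}

generate_clip_impl <- function(config, clip_id) {
  H <- config$image_size[1]; W <- config$image_size[2]
  n <- config$n_hands
  n <- if (is.null(n)) sample(seq_along(HANDS_PROBS), 1L, prob = HANDS_PROBS)
  else if (length(n) == 2L) {
    ch <- seq(n[1], n[2])
    ch[sample.int(length(ch), 1L)]
  } else as.integer(n)
  margin <- 0.22 * min(H, W)

  hands <- lapply(seq_len(n), function(i) {
    unit <- stats::runif(1, config$hand_scale[1], config$hand_scale[2]) * min(H, W)
    handedness <- sample(c("left", "right"), 1L)
    an <- sample_hand_anatomy(unit, handedness)
    list(an = an, handedness = handedness,
         col = config$glove_palette[[((i - 1L) %% length(config$glove_palette)) + 1L]],
         w = c(stats::runif(1, margin, W - margin), stats::runif(1, margin, H - margin)),
         heading = stats::runif(1, 0, 2 * pi),
         theta = stats::runif(1, 0, 2 * pi),
         phi = stats::runif(5, 0.1, 1.0),
         occ = NULL)
  })
  # occluder episode activation rate giving ~occlusion_prob occupancy
  edur <- 4.5
  qact <- if (config$occlusion_prob >= 1) 1 else
    min(1, config$occlusion_prob / (edur * (1 - config$occlusion_prob)))

  frames <- vector("list", config$n_frames)
  ann_frames <- vector("list", config$n_frames)
  masks_out <- if (config$keep_masks) vector("list", config$n_frames) else NULL
  background <- render_background(H, W)   # fixed camera: one backdrop per clip

  for (t in seq_len(config$n_frames)) {
    # advance dynamics (skip on the first frame so frame 1 shows init state)
    if (t > 1L) {
      for (i in seq_len(n)) {
        h <- hands[[i]]
        h$heading <- h$heading + stats::rnorm(1, 0, 0.3)
        step <- config$motion_speed * c(cos(h$heading), sin(h$heading))
        h$w <- h$w + step
        if (h$w[1] < margin || h$w[1] > W - margin) {
          h$heading <- pi - h$heading
          h$w[1] <- min(max(h$w[1], margin), W - margin)
        }
        if (h$w[2] < margin || h$w[2] > H - margin) {
          h$heading <- -h$heading
          h$w[2] <- min(max(h$w[2], margin), H - margin)
        }
        h$theta <- h$theta + stats::rnorm(1, 0, 0.06) * min(1, config$motion_speed)
        h$phi <- h$phi + stats::rnorm(5, 0, config$flexion_rate)
        h$phi <- pmin(pmax(h$phi, 0), 1.4)
        hands[[i]] <- h
      }
    }
    # occluder episodes
    for (i in seq_len(n)) {
      h <- hands[[i]]
      if (is.null(h$occ)) {
        if (stats::runif(1) < qact) {
          dur <- sample(3:6, 1L)
          wspan <- 1.6 * h$an$unit
          h$occ <- list(dur = dur, age = 0L,
                        size = c(stats::runif(1, 0.9, 1.5), stats::runif(1, 0.45, 0.8)) * h$an$unit,
                        from = -wspan, to = wspan,
                        dir = stats::runif(1, 0, 2 * pi),
                        col = stats::runif(3, 0.08, 0.35))
        }
      } else {
        h$occ$age <- h$occ$age + 1L
        if (h$occ$age >= h$occ$dur) h$occ <- NULL
      }
      hands[[i]] <- h
    }

    img <- background
    hand_masks <- vector("list", n)
    joints <- vector("list", n)
    for (i in seq_len(n)) {
      h <- hands[[i]]
      xy <- hand_joints(h$an, h$w, h$theta, h$phi)
      joints[[i]] <- xy
      z <- render_hand(img, h$an, xy, h$col)
      img <- z$img
      hand_masks[[i]] <- z$mask
    }
    # occluders drawn on top of every hand
    occ_mask <- matrix(FALSE, H, W)
    for (i in seq_len(n)) {
      h <- hands[[i]]
      if (is.null(h$occ)) next
      o <- h$occ
      frac <- o$age / max(1L, o$dur - 1L)
      offs <- o$from + frac * (o$to - o$from)
      ctr <- h$w + offs * c(cos(o$dir), sin(o$dir))
      x0 <- max(1L, floor(ctr[1] - o$size[1])); x1 <- min(W, ceiling(ctr[1] + o$size[1]))
      y0 <- max(1L, floor(ctr[2] - o$size[2])); y1 <- min(H, ceiling(ctr[2] + o$size[2]))
      if (x0 <= x1 && y0 <= y1) {
        for (ch in 1:3) img[y0:y1, x0:x1, ch] <- o$col[ch]
        occ_mask[y0:y1, x0:x1] <- TRUE
      }
    }

    # joint states and annotations
    hand_list <- list()
    for (i in seq_len(n)) {
      xy <- joints[[i]]
      st <- rep("visible", HT_J)
      px <- round(xy[, 1]); py <- round(xy[, 2])
      off <- px < 0 | px > W - 1 | py < 0 | py > H - 1
      st[off] <- "unannotated"
      for (j in which(!off)) {
        r <- py[j] + 1L; c <- px[j] + 1L
        covered <- occ_mask[r, c]
        if (!covered && i < n) {
          for (k in seq(i + 1L, n)) if (hand_masks[[k]][r, c]) { covered <- TRUE; break }
        }
        if (covered) st[j] <- "occluded"
      }
      ann <- st != "unannotated"
      if (!any(ann)) next
      pad <- 0.2 * hands[[i]]$an$unit
      b <- c(max(0, min(xy[ann, 1]) - pad), max(0, min(xy[ann, 2]) - pad),
             min(W, max(xy[ann, 1]) + pad), min(H, max(xy[ann, 2]) + pad))
      if (b[3] - b[1] < 2 || b[4] - b[2] < 2) next
      hand_list[[length(hand_list) + 1L]] <-
        hand_pose(xy = xy, state = st, handedness = hands[[i]]$handedness,
                  box = b, track_id = i - 1L)
    }

    frames[[t]] <- img
    ann_frames[[t]] <- list(frame_index = t - 1L,
                            image = sprintf("frames/%04d.png", t - 1L),
                            hands = hand_list)
    if (config$keep_masks)
      masks_out[[t]] <- list(hand_masks = hand_masks, occ_mask = occ_mask)
  }

  out <- list(frames = frames,
              annotation = clip_annotation(clip_id = clip_id, fps = 8,
                                           frames = ann_frames))
  if (config$keep_masks) out$masks <- masks_out
  out
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_clips` independent clips (seed derived from the config seed and
#' the clip index) under `out_dir`, one directory per clip with PNG frames
#' and an `annotation.json`, plus a `manifest.json` with the train/val split
#' (every fifth clip is validation).
#'
#' Hand counts across clips are drawn from the default distribution by
#' stratified allocation, so dataset-level statistics (mean hands per frame)
#' concentrate near their targets even for small `n_clips`.
#'
#' @param n_clips number of clips.
#' @param config a [synth_config()]; per-clip seeds derive from `config$seed`.
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return path to the manifest file, invisibly.
#' @export
generate_dataset <- function(n_clips, config, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    abort_ht(paste0("output directory not empty: ", out_dir), "ht_io_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- if (is.null(config$n_hands) && n_clips > 0) {
    with_rng_seed(derive_seed(config$seed, 777L), stratified_counts(n_clips))
  } else NULL
  entries <- vector("list", n_clips)
  for (i in seq_len(n_clips)) {
    cid <- sprintf("clip%03d", i - 1L)
    ccfg <- config
    ccfg$seed <- derive_seed(config$seed, i)
    if (!is.null(counts)) ccfg$n_hands <- counts[i]
    clip <- generate_clip(ccfg, clip_id = cid)
    cdir <- file.path(out_dir, cid)
    dir.create(file.path(cdir, "frames"), recursive = TRUE, showWarnings = FALSE)
    for (t in seq_along(clip$frames)) {
      png::writePNG(clip$frames[[t]],
                    file.path(cdir, sprintf("frames/%04d.png", t - 1L)))
    }
    save_clip(clip$annotation, file.path(cdir, "annotation.json"))
    entries[[i]] <- list(clip_id = jsonlite::unbox(cid),
                         dir = jsonlite::unbox(cid),
                         seed = jsonlite::unbox(ccfg$seed),
                         split = jsonlite::unbox(if (i %% 5L == 0L) "val" else "train"))
  }
  manifest <- list(clips = entries, n_clips = jsonlite::unbox(n_clips))
  mpath <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, null = "null", digits = NA), mpath)
  invisible(mpath)
}

stratified_counts <- function(n) {
  base <- floor(HANDS_PROBS * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- HANDS_PROBS * n - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  deck <- rep(seq_along(HANDS_PROBS), base)
  deck[sample.int(length(deck))]
}

#' Load a generated dataset's manifest
#' @param out_dir dataset directory written by [generate_dataset()].
#' @return list with per-clip ids, directories and split labels.
#' @export
load_manifest <- function(out_dir) {
  jsonlite::fromJSON(file.path(out_dir, "manifest.json"), simplifyVector = FALSE)
}

#' Read a clip's frames from disk
#' @param clip_dir clip directory containing `frames/` and `annotation.json`.
#' @return list with `annotation` and `frames`.
#' @export
read_clip_dir <- function(clip_dir) {
  ann <- load_clip(file.path(clip_dir, "annotation.json"))
  frames <- lapply(ann$frames, function(f) {
    img <- png::readPNG(file.path(clip_dir, f$image))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  list(annotation = ann, frames = frames)
}
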