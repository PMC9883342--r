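# Crop geometry, ground-truth heatmap encoding, decoding, masked MSE.
#
# Images are H x W x 3 arrays in [0, 1]. The crop window is centered on the
# hand box and covers `scale_factor` times the box area (each side scaled by
# sqrt(scale_factor), aspect preserved), then resampled to a fixed output
# size. Heatmaps live on a coarser H' x W' grid; the geometry object records
# the exact affine map between frame pixels, crop pixels and grid cells.

#' Crop a hand region from a frame
#'
#' @param image H x W x 3 numeric array in `[0, 1]`.
#' @param box hand bounding box in frame pixels.
#' @param scale_factor ratio of crop area to box area (default 2.2).
#' @param out_size output size in pixels as `c(H, W)` (default 256 x 256).
#' @return list with `image` (the resampled crop, zero-padded where the
#'   window leaves the frame) and `geom` (a `crop_geometry`).
#' @export
make_crop <- function(image, box, scale_factor = 2.2, out_size = c(256L, 256L)) {
  validate_box(box)
  d <- dim(image)
  if (box[1] >= d[2] || box[3] <= 0 || box[2] >= d[1] || box[4] <= 0)
    abort_ht("box lies entirely outside the image", "ht_geometry_error")
  ctr <- box_center(box)
  s <- sqrt(scale_factor)
  cw <- box_width(box) * s
  ch <- box_height(box) * s
  crop_box <- c(ctr[1] - cw / 2, ctr[2] - ch / 2, ctr[1] + cw / 2, ctr[2] + ch / 2)
  geom <- structure(list(source_box = as.numeric(box), scale_factor = scale_factor,
                         crop_box = crop_box, out_size = as.integer(out_size)),
                    class = "crop_geometry")
  # inverse map: output pixel centers -> frame coordinates
  xs <- (seq_len(out_size[2]) - 0.5) / out_size[2] * cw + crop_box[1]
  ys <- (seq_len(out_size[1]) - 0.5) / out_size[1] * ch + crop_box[2]
  crop <- bilinear_sample(image, xs, ys)
  list(image = crop, geom = geom)
}

# Bilinear sampling on a pixel-center grid, zero outside the image.
# xs, ys are frame coordinates of the requested pixel centers.
bilinear_sample <- function(image, xs, ys) {
  d <- dim(image)
  H <- d[1]; W <- d[2]; C <- if (length(d) == 3L) d[3] else 1L
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- array(0, c(length(ys), length(xs), C))
  imflat <- matrix(image, nrow = H * W, ncol = C)
  pick <- function(yi, xi) {
    # returns (length(ys) x length(xs)) x C values with zero padding
    okx <- xi >= 0 & xi <= W - 1
    oky <- yi >= 0 & yi <= H - 1
    xi2 <- pmin(pmax(xi, 0), W - 1)
    yi2 <- pmin(pmax(yi, 0), H - 1)
    idx <- outer(yi2 + 1, xi2 * H, "+")      # row-major into H x W (column-major)
    valid <- outer(oky, okx, "&")
    vals <- imflat[as.vector(idx), , drop = FALSE]
    vals[!as.vector(valid), ] <- 0
    vals
  }
  w00 <- outer(1 - fy, 1 - fx); w01 <- outer(1 - fy, fx)
  w10 <- outer(fy, 1 - fx);     w11 <- outer(fy, fx)
  acc <- pick(y0, x0) * as.vector(w00) + pick(y0, x0 + 1) * as.vector(w01) +
    pick(y0 + 1, x0) * as.vector(w10) + pick(y0 + 1, x0 + 1) * as.vector(w11)
  array(acc, c(length(ys), length(xs), C))
}

#' Map frame coordinates to crop pixel coordinates
#' @param geom a `crop_geometry` from [make_crop()].
#' @param xy n x 2 matrix of frame coordinates.
#' @return n x 2 matrix of crop pixel coordinates (0-based pixel centers).
#' @export
frame_to_crop <- function(geom, xy) {
  cb <- geom$crop_box
  cbind((xy[, 1] - cb[1]) / (cb[3] - cb[1]) * geom$out_size[2] - 0.5,
        (xy[, 2] - cb[2]) / (cb[4] - cb[2]) * geom$out_size[1] - 0.5)
}

#' Map crop pixel coordinates back to frame coordinates
#' @inheritParams frame_to_crop
#' @param xy n x 2 matrix of crop pixel coordinates.
#' @export
crop_to_frame <- function(geom, xy) {
  cb <- geom$crop_box
  cbind((xy[, 1] + 0.5) / geom$out_size[2] * (cb[3] - cb[1]) + cb[1],
        (xy[, 2] + 0.5) / geom$out_size[1] * (cb[4] - cb[2]) + cb[2])
}

frame_to_grid <- function(geom, xy, grid) {
  cb <- geom$crop_box
  cbind((xy[, 1] - cb[1]) / (cb[3] - cb[1]) * grid[2] - 0.5,
        (xy[, 2] - cb[2]) / (cb[4] - cb[2]) * grid[1] - 0.5)
}

grid_to_frame <- function(geom, xy, grid) {
  cb <- geom$crop_box
  cbind((xy[, 1] + 0.5) / grid[2] * (cb[3] - cb[1]) + cb[1],
        (xy[, 2] + 0.5) / grid[1] * (cb[4] - cb[2]) + cb[2])
}

#' Construct a heatmap stack
#'
#' @param values J x H' x W' numeric array of per-joint responses.
#' @param mask logical vector of length J; channels with `mask = FALSE` are
#'   excluded from the loss.
#' @return object of class `heatmap_stack`.
#' @export
heatmap_stack <- function(values, mask = rep(TRUE, dim(values)[1])) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L)
    abort_ht("heatmap values must be a J x H' x W' array", "ht_schema_error")
  if (length(mask) != d[1])
    abort_ht("heatmap mask length must equal the number of channels", "ht_schema_error")
  structure(list(values = values, mask = as.logical(mask)), class = "heatmap_stack")
}

zeros_heatmap <- function(grid, J = HT_J) {
  heatmap_stack(array(0, c(J, grid[1], grid[2])), mask = rep(TRUE, J))
}

#' Encode a pose as ground-truth Gaussian heatmaps
#'
#' Each annotated joint becomes an unnormalized 2D Gaussian on the heatmap
#' grid, centered on the joint's nearest grid cell so that the peak value is
#' exactly 1.0 there. Unannotated joints and joints falling outside the crop
#' window get a zero channel with `mask = FALSE`.
#'
#' @param pose a [hand_pose()] in frame coordinates.
#' @param geom `crop_geometry` of the crop the heatmaps refer to.
#' @param sigma_hm Gaussian standard deviation in heatmap-grid pixels.
#' @param grid heatmap grid size `c(H', W')`.
#' @return a [heatmap_stack()].
#' @export
encode_heatmaps <- function(pose, geom, sigma_hm = 2, grid = c(64L, 64L)) {
  if (!is.numeric(sigma_hm) || sigma_hm <= 0)
    abort_ht("sigma_hm must be positive", "ht_schema_error")
  J <- nrow(pose$xy)
  vals <- array(0, c(J, grid[1], grid[2]))
  mask <- rep(FALSE, J)
  g <- frame_to_grid(geom, pose$xy, grid)
  cells <- round(g)
  cols <- seq_len(grid[2]) - 1L
  rows <- seq_len(grid[1]) - 1L
  for (j in seq_len(J)) {
    if (pose$state[j] == "unannotated") next
    c0 <- cells[j, 1]; r0 <- cells[j, 2]
    if (!is.finite(c0) || !is.finite(r0) ||
        c0 < 0 || c0 > grid[2] - 1L || r0 < 0 || r0 > grid[1] - 1L) next
    mask[j] <- TRUE
    vals[j, , ] <- exp(-(outer((rows - r0)^2, (cols - c0)^2, "+")) / (2 * sigma_hm^2))
  }
  heatmap_stack(vals, mask)
}

#' Decode heatmaps to keypoints
#'
#' Per joint, the location is the center of the maximal grid cell mapped back
#' to frame coordinates and the confidence is the channel's maximum response.
#' Ties take the lowest row-major cell index.
#'
#' @param stack a [heatmap_stack()].
#' @param geom the crop geometry the stack was predicted in.
#' @return list with `xy` (J x 2 frame coordinates) and `confidence`.
#' @export
decode_heatmaps <- function(stack, geom) {
  d <- dim(stack$values)
  if (is.null(d) || d[1] < 1L) abort_ht("empty heatmap stack", "ht_schema_error")
  grid <- d[2:3]
  xy <- matrix(0, d[1], 2)
  conf <- numeric(d[1])
  for (j in seq_len(d[1])) {
    ch <- stack$values[j, , ]
    i0 <- which.max(t(ch))                 # row-major scan, first max wins
    r <- (i0 - 1L) %/% grid[2]
    c <- (i0 - 1L) %% grid[2]
    xy[j, ] <- grid_to_frame(geom, cbind(c, r), grid)
    conf[j] <- ch[r + 1L, c + 1L]
  }
  list(xy = xy, confidence = conf)
}

#' Masked mean squared error between heatmap stacks
#'
#' The mean runs over all cells of channels whose mask is `TRUE` on both
#' sides; if every channel is masked out the loss is 0.
#'
#' @param pred,gt [heatmap_stack()] objects of equal shape.
#' @return scalar loss.
#' @export
masked_mse <- function(pred, gt) {
  if (!identical(dim(pred$values), dim(gt$values)))
    abort_ht("heatmap shape mismatch", "ht_schema_error")
  m <- pred$mask & gt$mask
  if (!any(m)) return(0)
  diff <- pred$values[m, , , drop = FALSE] - gt$values[m, , , drop = FALSE]
  mean(diff^2)
}

# Gradient of masked_mse with respect to pred$values (same array shape).
masked_mse_grad <- function(pred, gt) {
  m <- pred$mask & gt$mask
  g <- array(0, dim(pred$values))
  if (!any(m)) return(g)
  n <- sum(m) * prod(dim(pred$values)[2:3])
  g[m, , ] <- 2 * (pred$values[m, , , drop = FALSE] - gt$values[m, , , drop = FALSE]) / n
  g
}

# ---- crop-space augmentation ------------------------------------------------

# Rotate a crop image and crop-space keypoints about the crop center.
# Joints rotated outside the crop are flagged.
rotate_crop <- function(img, xy_crop, angle) {
  d <- dim(img)
  cy <- (d[1] - 1) / 2; cx <- (d[2] - 1) / 2
  ca <- cos(angle); sa <- sin(angle)
  # inverse-rotate output pixel centers into the source image
  xs <- seq_len(d[2]) - 1; ys <- seq_len(d[1]) - 1
  gx <- outer(rep(1, d[1]), xs) - cx
  gy <- outer(ys, rep(1, d[2])) - cy
  sx <- ca * gx + sa * gy + cx
  sy <- -sa * gx + ca * gy + cy
  out <- bilinear_sample_points(img, sx, sy)
  nxy <- cbind(ca * (xy_crop[, 1] - cx) - sa * (xy_crop[, 2] - cy) + cx,
               sa * (xy_crop[, 1] - cx) + ca * (xy_crop[, 2] - cy) + cy)
  list(image = out, xy = nxy)
}

# Bilinear sampling at arbitrary (matrix-valued) coordinates.
bilinear_sample_points <- function(image, sx, sy) {
  d <- dim(image)
  H <- d[1]; W <- d[2]; C <- if (length(d) == 3L) d[3] else 1L
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  imflat <- matrix(image, nrow = H * W, ncol = C)
  pick <- function(yi, xi) {
    ok <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    xi2 <- pmin(pmax(xi, 0), W - 1); yi2 <- pmin(pmax(yi, 0), H - 1)
    idx <- yi2 + 1 + xi2 * H
    vals <- imflat[as.vector(idx), , drop = FALSE]
    vals[!as.vector(ok), ] <- 0
    vals
  }
  acc <- pick(y0, x0) * as.vector((1 - fy) * (1 - fx)) +
    pick(y0, x0 + 1) * as.vector((1 - fy) * fx) +
    pick(y0 + 1, x0) * as.vector(fy * (1 - fx)) +
    pick(y0 + 1, x0 + 1) * as.vector(fy * fx)
  array(acc, c(nrow(sx), ncol(sx), C))
}

flip_crop <- function(img, xy_crop) {
  d <- dim(img)
  list(image = img[, d[2]:1, , drop = FALSE],
       xy = cbind(d[2] - 1 - xy_crop[, 1], xy_crop[, 2]))
}
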