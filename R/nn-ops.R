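# Minimal dense/conv neural-network engine used by the pose network, the
# conditional head and the GCN embedder. Feature maps are numeric arrays
# with dim c(C, H, W) (channel fastest). All convolutions are 3x3, pad 1,
# stride 1; spatial down/up moves are explicit pooling/upsampling steps.
# Backward passes are hand-derived; optimization is Adam.

conv3_new <- function(cin, cout, gain = sqrt(2)) {
  sd <- gain / sqrt(cin * 9)
  list(W = matrix(stats::rnorm(cout * cin * 9, sd = sd), nrow = cout),
       b = numeric(cout))
}

conv3_fwd <- function(layer, x) {
  d <- dim(x)
  cols <- im2col3(as.numeric(x), d[1], d[2], d[3])
  y <- layer$W %*% cols + layer$b
  list(y = array(y, c(nrow(layer$W), d[2], d[3])), cols = cols, din = d)
}

conv3_bwd <- function(layer, fw, dy, need_dx = TRUE) {
  dym <- matrix(dy, nrow = dim(dy)[1])
  g <- list(W = dym %*% t(fw$cols), b = rowSums(dym))
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(layer$W, dym)
    dx <- col2im3(dcols, fw$din[1], fw$din[2], fw$din[3])
  }
  list(grad = g, dx = dx)
}

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(x, dy) dy * (x > 0)

# 2x2 max pooling (H, W even); gradient is routed to the first maximal cell
# in the fixed slice order for exact determinism.
maxpool2_fwd <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[2], 2L); co <- seq(1L, d[3], 2L)
  s <- list(x[, ro, co, drop = FALSE], x[, ro + 1L, co, drop = FALSE],
            x[, ro, co + 1L, drop = FALSE], x[, ro + 1L, co + 1L, drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(y = y, slices = s, din = d)
}

maxpool2_bwd <- function(fw, dy) {
  d <- fw$din
  y <- pmax(fw$slices[[1]], fw$slices[[2]], fw$slices[[3]], fw$slices[[4]])
  dx <- array(0, d)
  ro <- seq(1L, d[2], 2L); co <- seq(1L, d[3], 2L)
  taken <- array(FALSE, dim(y))
  put <- list(
    function(v) dx[, ro, co] <<- dx[, ro, co] + v,
    function(v) dx[, ro + 1L, co] <<- dx[, ro + 1L, co] + v,
    function(v) dx[, ro, co + 1L] <<- dx[, ro, co + 1L] + v,
    function(v) dx[, ro + 1L, co + 1L] <<- dx[, ro + 1L, co + 1L] + v)
  for (k in 1:4) {
    hit <- (fw$slices[[k]] == y) & !taken
    put[[k]](dy * hit)
    taken <- taken | hit
  }
  dx
}

# Area (block-mean) downsampling by an integer factor; for factor 2 this
# equals bilinear resampling at pixel centers. Used to bring early conv
# features onto the heatmap grid.
downsample_mean_fwd <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  acc <- 0
  for (dc in 0:(f - 1L)) for (dr in 0:(f - 1L)) {
    acc <- acc + x[, seq(1L + dr, d[2], f), seq(1L + dc, d[3], f), drop = FALSE]
  }
  acc / (f * f)
}

downsample_mean_bwd <- function(dy, f, din) {
  if (f == 1L) return(dy)
  dx <- array(0, din)
  g <- dy / (f * f)
  for (dc in 0:(f - 1L)) for (dr in 0:(f - 1L)) {
    dx[, seq(1L + dr, din[2], f), seq(1L + dc, din[3], f)] <- g
  }
  dx
}

cat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  tot <- sum(vapply(xs, function(x) dim(x)[1], 0))
  out <- array(0, c(tot, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    n <- dim(x)[1]
    out[at + seq_len(n), , ] <- x
    at <- at + n
  }
  out
}

split_channels <- function(x, sizes) {
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- x[at + seq_len(sizes[i]), , , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# ---- Adam over a flat named list of arrays ---------------------------------

adam_new <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Flatten a two-level parameter structure (layer -> W/b) into the flat list
# Adam works on, and back.
flatten_params <- function(layers) {
  out <- list()
  for (ln in names(layers)) for (pn in names(layers[[ln]])) {
    out[[paste(ln, pn, sep = ".")]] <- layers[[ln]][[pn]]
  }
  out
}

unflatten_params <- function(flat) {
  out <- list()
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    out[[parts[1]]][[parts[2]]] <- flat[[nm]]
  }
  out
}

zero_like <- function(params) lapply(params, function(p) p * 0)

acc_grads <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
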