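# Graph-convolutional pose embeddings for tracking-by-matching.
#
# A normalized pose (joints scaled to [0,1] within the hand box, optionally
# with an annotation-state channel) is embedded into 128 dimensions by a
# two-layer graph convolution over the hand-skeleton adjacency, trained with
# a contrastive loss so that the same hand in adjacent frames maps close and
# different hands map at least a margin apart.

#' Normalize a pose to its bounding box
#'
#' Coordinates become `(x - x0) / (x1 - x0)` (likewise y), clamped to
#' `[0, 1]`. With `C = 3` a third channel carries the annotation state: 0
#' for unannotated joints, 1 for annotated ground truth, or the predicted
#' confidence in `[0, 1]`.
#'
#' @param p a [hand_pose()].
#' @param C number of channels, 2 or 3.
#' @return J x C numeric matrix of class `normalized_pose`.
#' @export
normalize_pose <- function(p, C = 3L) {
  if (!C %in% c(2L, 3L)) abort_ht("C must be 2 or 3", "ht_schema_error")
  b <- p$box
  if (box_area(b) <= 0) abort_ht("zero-area box", "ht_schema_error")
  xs <- pmin(pmax((p$xy[, 1] - b[1]) / box_width(b), 0), 1)
  ys <- pmin(pmax((p$xy[, 2] - b[2]) / box_height(b), 0), 1)
  ann <- p$state != "unannotated"
  xs[!ann] <- 0; ys[!ann] <- 0
  X <- cbind(xs, ys)
  if (C == 3L) {
    st <- if (!is.null(p$confidence)) p$confidence else as.numeric(ann)
    st[!ann] <- 0
    X <- cbind(X, st)
  }
  X[!is.finite(X)] <- 0
  dimnames(X) <- NULL
  structure(X, class = "normalized_pose")
}

# Symmetrically normalized skeleton adjacency with self-loops.
skeleton_adjacency <- function() {
  A <- matrix(0, HT_J, HT_J)
  for (i in seq_len(nrow(HT_SKELETON))) {
    A[HT_SKELETON[i, 1], HT_SKELETON[i, 2]] <- 1
    A[HT_SKELETON[i, 2], HT_SKELETON[i, 1]] <- 1
  }
  A <- A + diag(HT_J)
  dinv <- 1 / sqrt(rowSums(A))
  A * outer(dinv, dinv)
}

#' GCN embedder configuration
#'
#' @param C input channels (2 = x,y; 3 adds annotation state).
#' @param hidden hidden widths of the two graph-convolution layers.
#' @param embed_dim output embedding dimension (default 128).
#' @param margin contrastive-loss margin.
#' @param loss_mode `"as_printed"` or `"standard"`, see
#'   [contrastive_loss()].
#' @param batch_size pairs per minibatch (default 32).
#' @param epochs training epochs (default 60).
#' @param steps_per_epoch minibatches drawn per epoch (default 50).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed.
#' @return object of class `gcn_config`.
#' @export
gcn_config <- function(C = 3L, hidden = c(32L, 64L), embed_dim = 128L,
                       margin = 1, loss_mode = "as_printed",
                       batch_size = 32L, epochs = 60L, steps_per_epoch = 50L,
                       lr = 1e-3, seed = 1L) {
  if (margin <= 0) abort_ht("margin must be positive", "ht_schema_error")
  structure(list(C = as.integer(C), hidden = as.integer(hidden),
                 embed_dim = as.integer(embed_dim), margin = margin,
                 loss_mode = loss_mode, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 lr = lr, seed = as.integer(seed)),
            class = "gcn_config")
}

#' Initialize a GCN embedder
#' @param cfg a [gcn_config()].
#' @return object of class `gcn_model`.
#' @export
gcn_init <- function(cfg) {
  par <- with_rng_seed(derive_seed(cfg$seed, 5L), list(
    g1 = list(W = matrix(stats::rnorm(cfg$C * cfg$hidden[1], sd = sqrt(2 / cfg$C)),
                         cfg$C, cfg$hidden[1]),
              b = numeric(cfg$hidden[1])),
    g2 = list(W = matrix(stats::rnorm(cfg$hidden[1] * cfg$hidden[2],
                                      sd = sqrt(2 / cfg$hidden[1])),
                         cfg$hidden[1], cfg$hidden[2]),
              b = numeric(cfg$hidden[2])),
    out = list(W = matrix(stats::rnorm(cfg$hidden[2] * cfg$embed_dim,
                                       sd = sqrt(1 / cfg$hidden[2])),
                          cfg$embed_dim, cfg$hidden[2]),
               b = numeric(cfg$embed_dim))))
  structure(list(cfg = cfg, par = par, A = skeleton_adjacency()),
            class = "gcn_model")
}

gcn_fwd_full <- function(model, X) {
  p <- model$par
  AX <- model$A %*% X
  Z1 <- AX %*% p$g1$W + matrix(p$g1$b, HT_J, length(p$g1$b), byrow = TRUE)
  H1 <- relu_fwd(Z1)
  AH <- model$A %*% H1
  Z2 <- AH %*% p$g2$W + matrix(p$g2$b, HT_J, length(p$g2$b), byrow = TRUE)
  H2 <- relu_fwd(Z2)
  pooled <- colMeans(H2)
  e <- as.numeric(p$out$W %*% pooled + p$out$b)
  list(e = e, AX = AX, Z1 = Z1, H1 = H1, AH = AH, Z2 = Z2, H2 = H2,
       pooled = pooled)
}

gcn_bwd_full <- function(model, fw, de) {
  p <- model$par
  dW3 <- outer(de, fw$pooled)
  db3 <- de
  dpooled <- as.numeric(crossprod(p$out$W, de))
  dH2 <- matrix(dpooled, HT_J, length(dpooled), byrow = TRUE) / HT_J
  dZ2 <- relu_bwd(fw$Z2, dH2)
  dW2 <- crossprod(fw$AH, dZ2)
  db2 <- colSums(dZ2)
  dH1 <- model$A %*% (dZ2 %*% t(p$g2$W))
  dZ1 <- relu_bwd(fw$Z1, dH1)
  dW1 <- crossprod(fw$AX, dZ1)
  db1 <- colSums(dZ1)
  list(g1 = list(W = dW1, b = db1), g2 = list(W = dW2, b = db2),
       out = list(W = dW3, b = db3))
}

#' Embed a normalized pose
#' @param model a `gcn_model`.
#' @param X a [normalize_pose()] matrix (J x C).
#' @return numeric embedding vector of length `embed_dim`.
#' @export
embed_pose <- function(model, X) {
  if (!is.matrix(X) || nrow(X) != HT_J || ncol(X) != model$cfg$C)
    abort_ht(sprintf("normalized pose must be %d x %d", HT_J, model$cfg$C),
             "ht_schema_error")
  gcn_fwd_full(model, unclass(X))$e
}

#' Contrastive loss between two embeddings
#'
#' `mode = "as_printed"` implements
#' `L = 1/2 (y d + (1 - y) max(0, (m - d)^2))` with `d` the *squared* L2
#' distance. `mode = "standard"` implements the textbook form
#' `L = 1/2 (y d^2 + (1 - y) max(0, m - d)^2)` with `d` the L2 distance.
#'
#' @param e1,e2 embedding vectors.
#' @param y 1 for the same hand, 0 for different hands.
#' @param m margin, positive.
#' @param mode `"as_printed"` (default) or `"standard"`.
#' @return scalar loss.
#' @export
contrastive_loss <- function(e1, e2, y, m, mode = "as_printed") {
  if (m <= 0) abort_ht("margin must be positive", "ht_schema_error")
  diff <- e1 - e2
  d2 <- sum(diff * diff)
  if (mode == "as_printed") {
    0.5 * (y * d2 + (1 - y) * max(0, (m - d2)^2))
  } else if (mode == "standard") {
    d <- sqrt(d2)
    0.5 * (y * d2 + (1 - y) * max(0, m - d)^2)
  } else {
    abort_ht("mode must be 'as_printed' or 'standard'", "ht_schema_error")
  }
}

# Gradient of contrastive_loss with respect to e1 (negate for e2).
contrastive_grad_e1 <- function(e1, e2, y, m, mode) {
  diff <- e1 - e2
  d2 <- sum(diff * diff)
  if (mode == "as_printed") {
    if (y == 1) diff else -2 * (m - d2) * diff
  } else {
    if (y == 1) diff
    else {
      d <- sqrt(d2)
      if (d >= m || d < 1e-12) numeric(length(e1)) else -(m - d) / d * diff
    }
  }
}

# Embedding distance in the geometry of the configured loss mode.
embedding_distance <- function(e1, e2, mode = "as_printed") {
  d2 <- sum((e1 - e2)^2)
  if (mode == "as_printed") d2 else sqrt(d2)
}

# Pair decision threshold: same hand iff the L2 distance is below margin/2,
# expressed in the loss geometry (squared for "as_printed").
pair_threshold <- function(cfg) {
  if (cfg$loss_mode == "as_printed") (cfg$margin / 2)^2 else cfg$margin / 2
}

# ---- pair sampling ----------------------------------------------------------

# Flat index of annotated hands: clip, frame position, frame index, track id.
pose_index <- function(clips) {
  rows <- list()
  for (ci in seq_along(clips)) {
    ann <- if (inherits(clips[[ci]], "clip_annotation")) clips[[ci]]
    else clips[[ci]]$annotation
    for (k in seq_along(ann$frames)) {
      fr <- ann$frames[[k]]
      for (hi in seq_along(fr$hands)) {
        h <- fr$hands[[hi]]
        rows[[length(rows) + 1L]] <-
          data.frame(clip = ci, fpos = k, frame = fr$frame_index, hand = hi,
                     track = h$track_id %||% NA_integer_)
      }
    }
  }
  do.call(rbind, rows)
}

get_pose <- function(clips, idx_row) {
  ann <- if (inherits(clips[[idx_row$clip]], "clip_annotation")) clips[[idx_row$clip]]
  else clips[[idx_row$clip]]$annotation
  ann$frames[[idx_row$fpos]]$hands[[idx_row$hand]]
}

#' Sample one training pair for the contrastive embedder
#'
#' The pair category is drawn with probabilities 0.5 / 0.4 / 0.1: a positive
#' pair (same track, adjacent frames, label 1), a negative pair from the
#' same clip (different tracks, label 0), or a negative pair from two
#' different clips (label 0). An infeasible category is redrawn among the
#' feasible ones.
#'
#' @param clips list of annotated clips with track ids.
#' @param C channels for [normalize_pose()].
#' @param index optional precomputed [pose_index()]-style table.
#' @return list with `X1`, `X2`, `y` and `category`.
#' @export
sample_training_pair <- function(clips, C = 3L, index = NULL) {
  idx <- index %||% pose_index(clips)
  cat_probs <- c(pos = 0.5, neg_same = 0.4, neg_diff = 0.1)
  for (attempt in 1:20) {
    category <- sample(names(cat_probs), 1L, prob = cat_probs)
    pair <- try_sample_pair(clips, idx, category)
    if (!is.null(pair)) {
      return(list(X1 = normalize_pose(pair$p1, C), X2 = normalize_pose(pair$p2, C),
                  y = pair$y, category = category))
    }
  }
  abort_ht("could not sample a pair; dataset too small or untracked", "ht_data_error")
}

try_sample_pair <- function(clips, idx, category) {
  if (category == "pos") {
    r1 <- idx[sample.int(nrow(idx), 1L), ]
    if (is.na(r1$track)) return(NULL)
    adj <- idx[idx$clip == r1$clip & idx$track == r1$track &
                 abs(idx$frame - r1$frame) == 1L, ]
    if (nrow(adj) == 0) return(NULL)
    r2 <- adj[sample.int(nrow(adj), 1L), ]
    list(p1 = get_pose(clips, r1), p2 = get_pose(clips, r2), y = 1)
  } else if (category == "neg_same") {
    r1 <- idx[sample.int(nrow(idx), 1L), ]
    others <- idx[idx$clip == r1$clip &
                    (is.na(idx$track) | is.na(r1$track) | idx$track != r1$track), ]
    if (nrow(others) == 0) return(NULL)
    r2 <- others[sample.int(nrow(others), 1L), ]
    list(p1 = get_pose(clips, r1), p2 = get_pose(clips, r2), y = 0)
  } else {
    if (length(clips) < 2L) return(NULL)
    cs <- sample.int(length(clips), 2L)
    a <- idx[idx$clip == cs[1], ]; b <- idx[idx$clip == cs[2], ]
    if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
    list(p1 = get_pose(clips, a[sample.int(nrow(a), 1L), ]),
         p2 = get_pose(clips, b[sample.int(nrow(b), 1L), ]), y = 0)
  }
}

#' Train the GCN pose embedder
#'
#' Pairs are drawn per the 0.5/0.4/0.1 scheme and optimized with Adam under
#' the contrastive loss. After each epoch, pair classification accuracy is
#' measured on a held-out pair set (decision rule: same hand iff the L2
#' embedding distance is below `margin / 2`).
#'
#' @param clips training clips with track ids.
#' @param cfg a [gcn_config()].
#' @param eval_clips clips for the held-out pairs (defaults to `clips`).
#' @param n_eval_pairs held-out pair count (default 300).
#' @return list with `model`, `accuracy` (per-epoch held-out accuracy) and
#'   `loss` (per-epoch mean training loss).
#' @export
train_gcn <- function(clips, cfg, eval_clips = NULL, n_eval_pairs = 300L) {
  if (length(clips) == 0) abort_ht("empty clip set", "ht_data_error")
  model <- gcn_init(cfg)
  idx <- pose_index(clips)
  if (is.null(idx) || nrow(idx) == 0) abort_ht("no annotated hands", "ht_data_error")
  eval_clips <- eval_clips %||% clips
  eidx <- pose_index(eval_clips)
  eval_pairs <- with_rng_seed(derive_seed(cfg$seed, 6L), {
    lapply(seq_len(n_eval_pairs), function(i)
      sample_training_pair(eval_clips, cfg$C, eidx))
  })
  flat <- flatten_params(model$par)
  opt <- adam_new(flat)
  acc_hist <- numeric(cfg$epochs)
  loss_hist <- numeric(cfg$epochs)
  thr <- pair_threshold(cfg)
  with_rng_seed(derive_seed(cfg$seed, 7L), {
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0; np <- 0L
      for (step in seq_len(cfg$steps_per_epoch)) {
        gacc <- zero_like(flat)
        for (bi in seq_len(cfg$batch_size)) {
          pr <- sample_training_pair(clips, cfg$C, idx)
          f1 <- gcn_fwd_full(model, unclass(pr$X1))
          f2 <- gcn_fwd_full(model, unclass(pr$X2))
          ep_loss <- ep_loss + contrastive_loss(f1$e, f2$e, pr$y, cfg$margin,
                                                cfg$loss_mode)
          np <- np + 1L
          de1 <- contrastive_grad_e1(f1$e, f2$e, pr$y, cfg$margin, cfg$loss_mode)
          g1 <- flatten_params(gcn_bwd_full(model, f1, de1))
          g2 <- flatten_params(gcn_bwd_full(model, f2, -de1))
          gacc <- acc_grads(gacc, acc_grads(g1, g2))
        }
        stp <- adam_step(flat, scale_grads(gacc, 1 / cfg$batch_size), opt, cfg$lr)
        flat <- stp$params; opt <- stp$state
        model$par <- unflatten_params(flat)
      }
      loss_hist[ep] <- ep_loss / max(1L, np)
      acc_hist[ep] <- pair_accuracy(model, eval_pairs, thr)
    }
  })
  list(model = model, accuracy = acc_hist, loss = loss_hist)
}

#' Pair classification accuracy of an embedder
#' @param model a `gcn_model`.
#' @param pairs list of pairs from [sample_training_pair()].
#' @param threshold decision threshold on the embedding distance in the loss
#'   geometry (defaults to an L2 distance of half the configured margin).
#' @return fraction of pairs classified correctly.
#' @export
pair_accuracy <- function(model, pairs, threshold = pair_threshold(model$cfg)) {
  ok <- vapply(pairs, function(pr) {
    d <- embedding_distance(embed_pose(model, pr$X1), embed_pose(model, pr$X2),
                            model$cfg$loss_mode)
    (d < threshold) == (pr$y == 1)
  }, TRUE)
  mean(ok)
}
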