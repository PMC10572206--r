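# The two-stage detector: shared backbone -> RPN (per-anchor objectness +
# deltas) -> proposal selection (clip, top-K, suppression, N = 600) ->
# position-sensitive head (voting + class-agnostic regression). Training
# alternates, per image, an RPN update and a head update; the backbone is
# updated by both. All randomness flows from the training seed.

#' Training configuration
#'
#' Defaults follow the reference optimization recipe: Adam with first-moment
#' coefficient 0.9, learning rate 5e-4 for 100 epochs with a single 0.1
#' decay, weight decay 5e-4; 2000 proposals before suppression and N = 600
#' after; RoIs are positive at IoU >= 0.5.
#'
#' @param lr Learning rate.
#' @param epochs Training epochs.
#' @param lr_decay Multiplicative decay factor applied once.
#' @param lr_decay_at Fraction of epochs after which the decay applies.
#' @param weight_decay L2 weight decay coefficient.
#' @param beta1 Adam first-moment ("momentum") coefficient.
#' @param beta2 Adam second-moment coefficient.
#' @param pre_nms,post_nms Proposal counts before/after suppression.
#' @param roi_pos_iou RoI positive-label IoU threshold.
#' @param roi_batch RoIs sampled per image for the head loss.
#' @param roi_pos_frac Maximum fraction of positives in the RoI sample.
#' @param rpn_batch Anchors sampled per image for the RPN loss.
#' @param augment Apply on-the-fly augmentation (uniform over identity,
#'   quarter-turn rotations, flips).
#' @param seed RNG seed for initialization, sampling and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 5e-4, epochs = 100, lr_decay = 0.1,
                         lr_decay_at = 0.75, weight_decay = 5e-4,
                         beta1 = 0.9, beta2 = 0.999,
                         pre_nms = 2000, post_nms = 600,
                         roi_pos_iou = 0.5, roi_batch = 128,
                         roi_pos_frac = 0.25, rpn_batch = 256,
                         augment = TRUE, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, weight_decay >= 0, post_nms <= pre_nms,
            roi_pos_iou > 0, roi_pos_iou < 1)
  structure(
    list(lr = lr, epochs = as.integer(epochs), lr_decay = lr_decay,
         lr_decay_at = lr_decay_at, weight_decay = weight_decay,
         beta1 = beta1, beta2 = beta2, pre_nms = pre_nms, post_nms = post_nms,
         roi_pos_iou = roi_pos_iou, roi_batch = roi_batch,
         roi_pos_frac = roi_pos_frac, rpn_batch = rpn_batch,
         augment = isTRUE(augment), seed = as.integer(seed)),
    class = "train_config"
  )
}

head_width <- function(arch) if (identical(arch, "mcs")) 512L else 64L

# the mcs backbone (stride 16, deep) uses the canonical 1x1 expansion before
# the position-sensitive heads; the stride-4 tiny backbone is so shallow
# that a 1x1 head cannot see whether a box covers a whole insect or a
# fragment, so its expansion uses a 3x3 kernel
head_kernel <- function(arch) if (identical(arch, "mcs")) 1L else 3L

init_detector_params <- function(bb, k, C, pspm_k) {
  ch <- bb$out_channels
  D <- head_width(bb$arch)
  p <- bb$params
  add <- function(p, name, c_in, c_out, kh = 1L, kw = 1L) {
    q <- init_conv_params(c_in, c_out, kh, kw)
    p[[paste0(name, "_W")]] <- q$W
    p[[paste0(name, "_b")]] <- q$b
    p
  }
  p <- add(p, "rpn_conv", ch, ch, 3L, 3L)
  p <- add(p, "rpn_cls", ch, 2L * k)
  p <- add(p, "rpn_reg", ch, 4L * k)
  hk <- head_kernel(bb$arch)
  p <- add(p, "head_conv", ch, D, hk, hk)
  p <- add(p, "ps_cls", D, pspm_k^2 * (C + 1L))
  p <- add(p, "ps_reg", D, 4L * pspm_k^2)
  p
}

param_groups <- function(bb) {
  backbone <- names(bb$params)
  list(
    backbone = backbone,
    rpn = c("rpn_conv_W", "rpn_conv_b", "rpn_cls_W", "rpn_cls_b",
            "rpn_reg_W", "rpn_reg_b"),
    head = c("head_conv_W", "head_conv_b", "ps_cls_W", "ps_cls_b",
             "ps_reg_W", "ps_reg_b")
  )
}

rpn_forward <- function(params, feat, k) {
  c1 <- conv_fwd(feat, params$rpn_conv_W, params$rpn_conv_b, 3L, 3L, 1L)
  r1 <- relu_fwd(c1$out)
  cls <- conv_fwd(r1$out, params$rpn_cls_W, params$rpn_cls_b, 1L, 1L, 0L)
  reg <- conv_fwd(r1$out, params$rpn_reg_W, params$rpn_reg_b, 1L, 1L, 0L)
  list(cls_map = cls$out, reg_map = reg$out,
       cache = list(c1 = c1, r1 = r1, cls = cls, reg = reg))
}

rpn_backward <- function(params, cache, d_cls_map, d_reg_map) {
  g <- list()
  b_cls <- conv_bwd(cache$cls$x, params$rpn_cls_W, d_cls_map, 1L, 1L, 0L)
  b_reg <- conv_bwd(cache$reg$x, params$rpn_reg_W, d_reg_map, 1L, 1L, 0L)
  g$rpn_cls_W <- b_cls$dW; g$rpn_cls_b <- b_cls$db
  g$rpn_reg_W <- b_reg$dW; g$rpn_reg_b <- b_reg$db
  dr1 <- relu_bwd(cache$r1$mask, b_cls$dx + b_reg$dx)
  b_c1 <- conv_bwd(cache$c1$x, params$rpn_conv_W, dr1, 3L, 3L, 1L)
  g$rpn_conv_W <- b_c1$dW; g$rpn_conv_b <- b_c1$db
  list(grads = g, dfeat = b_c1$dx)
}

head_forward <- function(params, feat, pspm_k, C) {
  hk <- as.integer(round(sqrt(ncol(params$head_conv_W) / dim(feat)[3])))
  c1 <- conv_fwd(feat, params$head_conv_W, params$head_conv_b, hk, hk,
                 (hk - 1L) %/% 2L)
  r1 <- relu_fwd(c1$out)
  cls <- conv_fwd(r1$out, params$ps_cls_W, params$ps_cls_b, 1L, 1L, 0L)
  reg <- conv_fwd(r1$out, params$ps_reg_W, params$ps_reg_b, 1L, 1L, 0L)
  list(cls_maps = cls$out, reg_maps = reg$out,
       cache = list(c1 = c1, r1 = r1, cls = cls, reg = reg))
}

head_backward <- function(params, cache, d_cls_maps, d_reg_maps) {
  g <- list()
  b_cls <- conv_bwd(cache$cls$x, params$ps_cls_W, d_cls_maps, 1L, 1L, 0L)
  b_reg <- conv_bwd(cache$reg$x, params$ps_reg_W, d_reg_maps, 1L, 1L, 0L)
  g$ps_cls_W <- b_cls$dW; g$ps_cls_b <- b_cls$db
  g$ps_reg_W <- b_reg$dW; g$ps_reg_b <- b_reg$db
  dr1 <- relu_bwd(cache$r1$mask, b_cls$dx + b_reg$dx)
  hk <- as.integer(round(sqrt(ncol(params$head_conv_W) / dim(cache$c1$x)[3])))
  b_c1 <- conv_bwd(cache$c1$x, params$head_conv_W, dr1, hk, hk,
                   (hk - 1L) %/% 2L)
  g$head_conv_W <- b_c1$dW; g$head_conv_b <- b_c1$db
  list(grads = g, dfeat = b_c1$dx)
}

# flatten H x W x (m*k) maps to an (H*W*k) x m matrix in anchor order
# (cells row-major, the k per-cell anchors innermost)
flatten_anchor_maps <- function(map, k, m) {
  H <- dim(map)[1]; W <- dim(map)[2]
  n <- H * W * k
  out <- matrix(0, n, m)
  for (a in seq_len(k)) {
    rows <- seq(a, n, by = k)
    for (j in seq_len(m)) {
      out[rows, j] <- as.vector(t(map[, , m * (a - 1) + j]))
    }
  }
  out
}

unflatten_anchor_maps <- function(flat, H, W, k, m) {
  out <- array(0, c(H, W, k * m))
  n <- H * W * k
  for (a in seq_len(k)) {
    rows <- seq(a, n, by = k)
    for (j in seq_len(m)) {
      out[, , m * (a - 1) + j] <- t(matrix(flat[rows, j], W, H))
    }
  }
  out
}

# map an image-space box to integer feature-map cells (x0, y0, w, h)
box_to_feature_roi <- function(boxes, stride, feat_w, feat_h) {
  b <- box_matrix(boxes)
  x0 <- pmin(pmax(floor(b[, 1] / stride), 0), feat_w - 1)
  y0 <- pmin(pmax(floor(b[, 2] / stride), 0), feat_h - 1)
  x1 <- pmax(pmin(ceiling(b[, 3] / stride), feat_w), x0 + 1)
  y1 <- pmax(pmin(ceiling(b[, 4] / stride), feat_h), y0 + 1)
  cbind(fx0 = x0, fy0 = y0, fw = x1 - x0, fh = y1 - y0)
}

#' Select region proposals from RPN outputs
#'
#' Decodes deltas onto anchors, clips to the image, drops degenerate boxes,
#' keeps the top `pre_nms` by objectness, applies the configured suppression,
#' and returns at most `post_nms` proposals sorted by (decayed) score, with
#' both image-space boxes and integer feature-map RoIs.
#'
#' @param objectness Foreground score per anchor.
#' @param deltas n x 4 matrix of predicted deltas in anchor order.
#' @param anchors Anchor table from [generate_anchors()].
#' @param image_w,image_h Image dimensions.
#' @param stride Backbone stride (to express RoIs in feature cells).
#' @param suppression A [suppression_config()].
#' @param pre_nms,post_nms Proposal budget before/after suppression.
#' @param min_size Minimum longer side of a proposal, pixels; boxes decoding
#'   below the smallest anchor scale are spurious and are dropped.
#' @return Tibble with xmin..ymax (image pixels), score, fx0, fy0, fw, fh.
#' @export
propose_rois <- function(objectness, deltas, anchors, image_w, image_h,
                         stride, suppression = suppression_config(),
                         pre_nms = 2000, post_nms = 600, min_size = 0) {
  boxes <- decode_boxes(deltas, anchors)
  cl <- clip_boxes(boxes, image_w, image_h)
  long_side <- pmax(cl$xmax - cl$xmin, cl$ymax - cl$ymin)
  ok <- which(!cl$degenerate & long_side >= min_size)
  if (length(ok) == 0L) {
    return(tibble(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                  ymax = numeric(), score = numeric(), fx0 = integer(),
                  fy0 = integer(), fw = integer(), fh = integer()))
  }
  ord <- ok[order(objectness[ok], decreasing = TRUE)]
  keep <- head(ord, pre_nms)
  cand <- tibble(
    xmin = cl$xmin[keep], ymin = cl$ymin[keep],
    xmax = cl$xmax[keep], ymax = cl$ymax[keep],
    score = objectness[keep]
  )
  supp <- if (suppression$mode == "hard") {
    hard_nms(cand, suppression$Nt)
  } else {
    soft_nms(cand, suppression)
  }
  supp <- head(supp[order(supp$score, decreasing = TRUE), ], post_nms)
  feat_w <- as.integer(ceiling(image_w / stride))
  feat_h <- as.integer(ceiling(image_h / stride))
  fr <- box_to_feature_roi(supp, stride, feat_w, feat_h)
  dplyr::bind_cols(supp, as_tibble(fr))
}

balanced_cross_entropy <- function(probs, labels, is_fg) {
  p <- probs[cbind(seq_len(nrow(probs)), labels)]
  sum(class_balance_weights(is_fg) * -log(pmax(p, 1e-12)))
}

#' Detector loss components
#'
#' Class-balanced cross-entropy for the RPN objectness and the head
#' classification (computed from predicted probabilities; foreground and
#' background samples carry equal total weight, so scarce positives are not
#' drowned out), smooth-L1 on box deltas for positive samples only.
#' `total` is the plain sum of the four parts.
#'
#' @param rpn List with `probs` (n x 2, columns background/foreground) and
#'   `deltas` (n x 4) for the sampled anchors.
#' @param head List with `probs` (m x (C+1), background last) and `deltas`
#'   (m x 4) for the sampled RoIs.
#' @param rpn_match List with `labels` (factor positive/negative over the
#'   sampled anchors) and `targets` (n x 4 encoded deltas, rows used for
#'   positives).
#' @param rois List with `labels` (integer class per sampled RoI, C+1 =
#'   background), `targets` (m x 4 encoded deltas), and optionally
#'   `loc_mask` (indices of RoIs carrying a regression target; defaults to
#'   the foreground RoIs).
#' @return List rpn_cls, rpn_loc, roi_cls, roi_loc, total.
#' @export
compute_losses <- function(rpn, head, rpn_match, rois) {
  lab <- as.character(rpn_match$labels)
  if (!any(lab %in% c("positive", "negative"))) {
    abort("RPN classification loss undefined: no positive or negative anchors")
  }
  use <- lab %in% c("positive", "negative")
  cls_target <- ifelse(lab[use] == "positive", 2L, 1L)
  rpn_cls <- balanced_cross_entropy(rpn$probs[use, , drop = FALSE],
                                    cls_target, cls_target == 2L)
  pos <- which(lab == "positive")
  rpn_loc <- if (length(pos)) {
    d <- rpn$deltas[pos, , drop = FALSE] - rpn_match$targets[pos, , drop = FALSE]
    sum(apply(d, 1, smooth_l1)) / length(pos)
  } else 0
  roi_cls <- balanced_cross_entropy(head$probs, rois$labels,
                                    rois$labels < ncol(head$probs))
  fg <- rois$loc_mask %||% which(rois$labels < ncol(head$probs))
  roi_loc <- if (length(fg)) {
    d <- head$deltas[fg, , drop = FALSE] - rois$targets[fg, , drop = FALSE]
    sum(apply(d, 1, smooth_l1)) / length(fg)
  } else 0
  list(rpn_cls = rpn_cls, rpn_loc = rpn_loc,
       roi_cls = roi_cls, roi_loc = roi_loc,
       total = rpn_cls + rpn_loc + roi_cls + roi_loc)
}

# per-sample weights giving foreground and background halves equal mass
# (falls back to uniform when one side is absent); weights sum to 1
class_balance_weights <- function(is_fg) {
  n <- length(is_fg)
  n_fg <- sum(is_fg)
  if (n_fg == 0L || n_fg == n) return(rep(1 / n, n))
  ifelse(is_fg, 0.5 / n_fg, 0.5 / (n - n_fg))
}

sample_balanced <- function(pos_idx, neg_idx, batch, pos_frac) {
  n_pos <- min(length(pos_idx), round(batch * pos_frac))
  pos <- if (length(pos_idx) > n_pos) sample(pos_idx, n_pos) else pos_idx
  n_neg <- min(length(neg_idx), batch - length(pos))
  neg <- if (length(neg_idx) > n_neg) sample(neg_idx, n_neg) else neg_idx
  list(pos = pos, neg = neg)
}

gt_matrix <- function(record) {
  ann <- record$annotations
  ann <- ann[!ann$difficult, , drop = FALSE]
  list(boxes = box_matrix(ann), labels = ann$label)
}

#' Count trainable parameters by pipeline stage
#'
#' All trainable parameters live in the backbone, the RPN, and the two 1x1
#' head stacks producing the position-sensitive maps; pooling, voting and
#' suppression after the RoI stage are parameter-free.
#'
#' @param model A `grain_detector`.
#' @return Tibble with columns stage, parameter, n.
#' @export
parameter_inventory <- function(model) {
  groups <- param_groups(model$backbone)
  purrr::map_dfr(names(groups), function(g) {
    nm <- intersect(groups[[g]], names(model$params))
    tibble(stage = g, parameter = nm,
           n = purrr::map_int(model$params[nm], length))
  })
}

#' Train the two-stage detector
#'
#' For each image in each epoch, performs an RPN update step (objectness +
#' anchor-delta losses against matched anchors) and then a head update step
#' (class voting + class-agnostic regression losses on sampled RoIs from the
#' current proposals); the shared backbone is updated in both. Ground-truth
#' boxes are appended to the proposal pool during training so the head sees
#' positive RoIs from the first epoch. Difficult annotations are never
#' training targets.
#'
#' @param dataset List of `grain_record`s, or a manifest path.
#' @param config A [train_config()].
#' @param anchors An [anchor_config()] (stride is overridden by the
#'   backbone's stride).
#' @param suppression A [suppression_config()] used for proposal pruning.
#' @param pspm_k Position-sensitive bin grid size.
#' @param arch Backbone architecture, `"tiny"` or `"mcs"`.
#' @param classes Class vocabulary; defaults to the sorted labels present.
#' @param verbose Print per-epoch loss components.
#' @return A `grain_detector` (parameters, configs, per-epoch loss history).
#' @export
train_detector <- function(dataset, config = train_config(),
                           anchors = anchor_config(),
                           suppression = suppression_config(),
                           pspm_k = 3L, arch = "tiny", classes = NULL,
                           verbose = FALSE) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  stopifnot(length(dataset) >= 1)
  all_ann <- flatten_annotations(dataset)
  usable <- all_ann[!all_ann$difficult, , drop = FALSE]
  if (nrow(usable) == 0L) {
    abort("training requires at least one non-difficult annotation")
  }
  if (is.null(classes)) classes <- sort(unique(usable$label))
  C <- length(classes)
  set.seed(config$seed)
  bb <- build_backbone(arch)
  anchors <- anchor_config(anchors$scales, anchors$ratios, stride = bb$stride)
  k <- anchors$k
  params <- init_detector_params(bb, k, C, pspm_k)
  state <- adam_init(params)
  history <- list()
  n_img <- length(dataset)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr *
      if (epoch > ceiling(config$lr_decay_at * config$epochs)) config$lr_decay else 1
    ep_loss <- c(rpn_cls = 0, rpn_loc = 0, roi_cls = 0, roi_loc = 0)
    ep_n <- c(rpn = 0L, roi = 0L)
    for (ii in sample.int(n_img)) {
      rec <- dataset[[ii]]
      if (config$augment) {
        op <- sample(c("identity", augment_ops), 1L)
        if (op != "identity") rec <- augment_record(rec, op)
      }
      gt <- gt_matrix(rec)
      step <- train_step_rpn(bb, params, state, rec, gt, anchors, config, lr)
      params <- step$params; state <- step$state
      if (!is.null(step$loss)) {
        ep_loss["rpn_cls"] <- ep_loss["rpn_cls"] + step$loss$rpn_cls
        ep_loss["rpn_loc"] <- ep_loss["rpn_loc"] + step$loss$rpn_loc
        ep_n["rpn"] <- ep_n["rpn"] + 1L
      }
      step <- train_step_head(bb, params, state, rec, gt, anchors, config,
                              suppression, pspm_k, classes, lr)
      params <- step$params; state <- step$state
      if (!is.null(step$loss)) {
        ep_loss["roi_cls"] <- ep_loss["roi_cls"] + step$loss$roi_cls
        ep_loss["roi_loc"] <- ep_loss["roi_loc"] + step$loss$roi_loc
        ep_n["roi"] <- ep_n["roi"] + 1L
      }
    }
    row <- tibble(
      epoch = epoch,
      rpn_cls = ep_loss["rpn_cls"] / max(1L, ep_n["rpn"]),
      rpn_loc = ep_loss["rpn_loc"] / max(1L, ep_n["rpn"]),
      roi_cls = ep_loss["roi_cls"] / max(1L, ep_n["roi"]),
      roi_loc = ep_loss["roi_loc"] / max(1L, ep_n["roi"])
    )
    row$total <- row$rpn_cls + row$rpn_loc + row$roi_cls + row$roi_loc
    history[[epoch]] <- row
    if (verbose) {
      message(sprintf(
        "epoch %3d  rpn_cls %.4f  rpn_loc %.4f  roi_cls %.4f  roi_loc %.4f",
        epoch, row$rpn_cls, row$rpn_loc, row$roi_cls, row$roi_loc
      ))
    }
  }
  bb$params <- params[names(bb$params)]
  structure(
    list(params = params, backbone = bb, classes = classes,
         anchors = anchors, suppression = suppression,
         pspm_k = as.integer(pspm_k), train_config = config,
         history = dplyr::bind_rows(history)),
    class = "grain_detector"
  )
}

train_step_rpn <- function(bb, params, state, rec, gt, anchors, config, lr) {
  bb$params <- params[names(bb$params)]
  fwd <- backbone_forward(bb, rec$pixels, bb$params)
  H <- dim(fwd$feat)[1]; W <- dim(fwd$feat)[2]
  rpn <- rpn_forward(params, fwd$feat, anchors$k)
  agrid <- generate_anchors(anchors, W, H, rec$width, rec$height, "train")
  mt <- match_anchors(agrid$anchors, agrid$valid, gt$boxes)
  pos_idx <- which(mt$labels == "positive")
  neg_idx <- which(mt$labels == "negative")
  if (length(pos_idx) + length(neg_idx) == 0L) {
    return(list(params = params, state = state, loss = NULL))
  }
  samp <- sample_balanced(pos_idx, neg_idx, config$rpn_batch, 0.5)
  sel <- c(samp$pos, samp$neg)
  n_samp <- length(sel)
  logits <- flatten_anchor_maps(rpn$cls_map, anchors$k, 2L)
  deltas <- flatten_anchor_maps(rpn$reg_map, anchors$k, 4L)
  probs <- softmax_rows(logits[sel, , drop = FALSE])
  y <- ifelse(seq_len(n_samp) <= length(samp$pos), 2L, 1L)
  # gradients w.r.t. logits and deltas; positive and negative anchors carry
  # equal total weight so the scarce positives are not drowned out
  n_anchor <- nrow(logits)
  dlogit <- matrix(0, n_anchor, 2L)
  onehot <- matrix(0, n_samp, 2L)
  onehot[cbind(seq_len(n_samp), y)] <- 1
  wts <- class_balance_weights(y == 2L)
  dlogit[sel, ] <- (probs - onehot) * wts
  ddelta <- matrix(0, n_anchor, 4L)
  targets <- matrix(0, n_samp, 4L)
  if (length(samp$pos)) {
    tgt <- encode_boxes(gt$boxes[mt$matched_gt[samp$pos], , drop = FALSE],
                        agrid$anchors[samp$pos, , drop = FALSE])
    tgt <- as.matrix(tgt)
    targets[seq_along(samp$pos), ] <- tgt
    dd <- smooth_l1_grad(deltas[samp$pos, , drop = FALSE] - tgt) /
      length(samp$pos)
    ddelta[samp$pos, ] <- dd
  }
  loss <- compute_losses(
    rpn = list(probs = probs, deltas = deltas[sel, , drop = FALSE]),
    head = list(probs = matrix(1, 1, 2), deltas = matrix(0, 1, 4)),
    rpn_match = list(
      labels = factor(ifelse(y == 2L, "positive", "negative"),
                      c("positive", "negative", "ignore")),
      targets = targets
    ),
    rois = list(labels = 2L, targets = matrix(0, 1, 4))
  )
  d_cls_map <- unflatten_anchor_maps(dlogit, H, W, anchors$k, 2L)
  d_reg_map <- unflatten_anchor_maps(ddelta, H, W, anchors$k, 4L)
  rb <- rpn_backward(params, rpn$cache, d_cls_map, d_reg_map)
  bbb <- backbone_backward(bb, fwd$cache, rb$dfeat, bb$params)
  upd <- adam_step(params, c(rb$grads, bbb$grads), state, lr,
                   config$weight_decay, config$beta1, config$beta2)
  list(params = upd$params, state = upd$state,
       loss = list(rpn_cls = loss$rpn_cls, rpn_loc = loss$rpn_loc))
}

train_step_head <- function(bb, params, state, rec, gt, anchors, config,
                            suppression, pspm_k, classes, lr) {
  C <- length(classes)
  if (nrow(gt$boxes) == 0L) {
    return(list(params = params, state = state, loss = NULL))
  }
  bb$params <- params[names(bb$params)]
  fwd <- backbone_forward(bb, rec$pixels, bb$params)
  H <- dim(fwd$feat)[1]; W <- dim(fwd$feat)[2]
  rpn <- rpn_forward(params, fwd$feat, anchors$k)
  agrid <- generate_anchors(anchors, W, H, rec$width, rec$height, "test")
  logits <- flatten_anchor_maps(rpn$cls_map, anchors$k, 2L)
  objectness <- softmax_rows(logits)[, 2]
  deltas <- flatten_anchor_maps(rpn$reg_map, anchors$k, 4L)
  props <- propose_rois(objectness, deltas, agrid$anchors,
                        rec$width, rec$height, anchors$stride, suppression,
                        config$pre_nms, config$post_nms,
                        min_size = min(anchors$scales))
  # append ground-truth boxes plus jittered copies so positives exist from
  # the first epoch and span the IoU in [0.5, 1] range with non-trivial
  # regression targets (otherwise the head only ever sees perfect boxes)
  g <- gt$boxes
  jitter_one <- function(mat, shift = 0.15, scale = 0.25) {
    w <- mat[, 3] - mat[, 1]; h <- mat[, 4] - mat[, 2]
    cx <- mat[, 1] + w / 2 + runif(nrow(mat), -shift, shift) * w
    cy <- mat[, 2] + h / 2 + runif(nrow(mat), -shift, shift) * h
    w <- w * exp(runif(nrow(mat), -scale, scale))
    h <- h * exp(runif(nrow(mat), -scale, scale))
    out <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    cl <- clip_boxes(out, rec$width, rec$height)
    as.matrix(cl[!cl$degenerate, 1:4])
  }
  gmat <- rbind(g, jitter_one(g), jitter_one(g), jitter_one(g, 0.3, 0.4))
  gt_rois <- tibble(
    xmin = gmat[, 1], ymin = gmat[, 2],
    xmax = gmat[, 3], ymax = gmat[, 4], score = 1
  )
  fr <- box_to_feature_roi(gt_rois, anchors$stride, W, H)
  pool <- dplyr::bind_rows(props, dplyr::bind_cols(gt_rois, as_tibble(fr)))
  M <- iou_matrix(pool, gt$boxes)
  best <- max.col(M, ties.method = "first")
  best_iou <- M[cbind(seq_len(nrow(pool)), best)]
  pos_idx <- which(best_iou >= config$roi_pos_iou)
  # background RoIs are drawn preferentially from near misses (IoU in
  # [0.1, pos_iou)): these are the hard negatives that teach the head to
  # rank a badly-aligned box below a well-aligned one
  hard_neg <- which(best_iou < config$roi_pos_iou & best_iou >= 0.1)
  easy_neg <- which(best_iou < 0.1)
  n_pos <- min(length(pos_idx), round(config$roi_batch * config$roi_pos_frac))
  pos <- if (length(pos_idx) > n_pos) sample(pos_idx, n_pos) else pos_idx
  n_neg <- config$roi_batch - length(pos)
  n_hard <- min(length(hard_neg), round(0.5 * n_neg))
  hard <- if (length(hard_neg) > n_hard) sample(hard_neg, n_hard) else hard_neg
  n_easy <- min(length(easy_neg), n_neg - length(hard))
  easy <- if (length(easy_neg) > n_easy) sample(easy_neg, n_easy) else easy_neg
  samp <- list(pos = pos, neg = c(hard, easy))
  sel <- c(samp$pos, samp$neg)
  if (length(sel) == 0L) {
    return(list(params = params, state = state, loss = NULL))
  }
  head <- head_forward(params, fwd$feat, pspm_k, C)
  rois <- as.matrix(pool[sel, c("fx0", "fy0", "fw", "fh")])
  ps <- ps_heads_forward(head$cls_maps, head$reg_maps, rois, pspm_k, C)
  probs <- softmax_rows(ps$r)
  m <- length(sel)
  labels <- rep(C + 1L, m)
  if (length(samp$pos)) {
    labels[seq_along(samp$pos)] <- match(gt$labels[best[samp$pos]], classes)
  }
  targets <- matrix(0, m, 4L)
  # the regression branch trains on a wider IoU band (>= 0.3) than the
  # classifier: fragment boxes must learn the expansion that snaps them
  # onto the full object even though they are labeled background
  reg_fg <- which(best_iou[sel] >= 0.3)
  if (length(reg_fg)) {
    targets[reg_fg, ] <- as.matrix(encode_boxes(
      gt$boxes[best[sel[reg_fg]], , drop = FALSE],
      pool[sel[reg_fg], c("xmin", "ymin", "xmax", "ymax")]
    ))
  }
  loss <- compute_losses(
    rpn = list(probs = matrix(c(0, 1), 1, 2), deltas = matrix(0, 1, 4)),
    head = list(probs = probs, deltas = ps$t),
    rpn_match = list(labels = factor("negative",
                                     c("positive", "negative", "ignore")),
                     targets = matrix(0, 1, 4)),
    rois = list(labels = labels, targets = targets, loc_mask = reg_fg)
  )
  onehot <- matrix(0, m, C + 1L)
  onehot[cbind(seq_len(m), labels)] <- 1
  dr <- (probs - onehot) * class_balance_weights(labels <= C)
  dt <- matrix(0, m, 4L)
  if (length(reg_fg)) {
    dt[reg_fg, ] <- smooth_l1_grad(ps$t[reg_fg, , drop = FALSE] -
                                     targets[reg_fg, , drop = FALSE]) /
      length(reg_fg)
  }
  dmaps <- ps_heads_backward(dim(head$cls_maps), dim(head$reg_maps),
                             rois, pspm_k, C, dr, dt)
  hb <- head_backward(params, head$cache, dmaps$d_cls, dmaps$d_reg)
  bbb <- backbone_backward(bb, fwd$cache, hb$dfeat, bb$params)
  upd <- adam_step(params, c(hb$grads, bbb$grads), state, lr,
                   config$weight_decay, config$beta1, config$beta2)
  list(params = upd$params, state = upd$state,
       loss = list(roi_cls = loss$roi_cls, roi_loc = loss$roi_loc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run detection on an image
#'
#' Backbone, RPN proposals (all anchors valid, boxes clipped), iterative
#' class-agnostic box refinement, position-sensitive voting at the refined
#' box, then per-class suppression. The background class is never emitted;
#' scores are softmax probabilities.
#'
#' @param image A `grain_record` or an `H x W x 3` pixel array.
#' @param model A `grain_detector` from [train_detector()].
#' @param suppression Suppression config for final detections (defaults to
#'   the model's).
#' @param score_thresh Minimum emitted score.
#' @param n_refine Number of iterative box-refinement passes (each pass
#'   pools the regression maps at the current box and decodes; the head is
#'   parameter-free so this adds pooling work only).
#' @return Detection tibble: image_id, label, score, xmin, ymin, xmax, ymax.
#' @export
detect <- function(image, model, suppression = model$suppression,
                   score_thresh = 0.05, n_refine = 4L) {
  stopifnot(inherits(model, "grain_detector"))
  if (inherits(image, "grain_record")) {
    px <- image$pixels
    id <- image$id
  } else {
    px <- image
    id <- "image"
  }
  if (dim(px)[1] < model$backbone$stride || dim(px)[2] < model$backbone$stride) {
    abort("image smaller than the backbone stride")
  }
  image_h <- dim(px)[1]; image_w <- dim(px)[2]
  bb <- model$backbone
  bb$params <- model$params[names(bb$params)]
  fwd <- backbone_forward(bb, px, bb$params)
  H <- dim(fwd$feat)[1]; W <- dim(fwd$feat)[2]
  k <- model$anchors$k
  C <- length(model$classes)
  rpn <- rpn_forward(model$params, fwd$feat, k)
  agrid <- generate_anchors(model$anchors, W, H, image_w, image_h, "test")
  objectness <- softmax_rows(flatten_anchor_maps(rpn$cls_map, k, 2L))[, 2]
  deltas <- flatten_anchor_maps(rpn$reg_map, k, 4L)
  props <- propose_rois(objectness, deltas, agrid$anchors, image_w, image_h,
                        model$anchors$stride, model$suppression,
                        model$train_config$pre_nms, model$train_config$post_nms,
                        min_size = min(model$anchors$scales))
  empty <- tibble(image_id = character(), label = character(),
                  score = numeric(), xmin = numeric(), ymin = numeric(),
                  xmax = numeric(), ymax = numeric())
  if (nrow(props) == 0L) return(empty)
  head_out <- head_forward(model$params, fwd$feat, model$pspm_k, C)
  # iteratively refine each proposal with the class-agnostic regression
  # (everything after the RoI stage is parameter-free, so each pass is just
  # another pooling), then score the box that is actually emitted by
  # pooling the class maps at its final location
  boxes <- props[, c("xmin", "ymin", "xmax", "ymax")]
  dead <- rep(FALSE, nrow(boxes))
  for (it in seq_len(max(1L, n_refine))) {
    rois <- box_to_feature_roi(boxes, model$anchors$stride, W, H)
    ps <- ps_heads_forward(head_out$cls_maps, head_out$reg_maps, rois,
                           model$pspm_k, C)
    cl <- clip_boxes(decode_boxes(ps$t, boxes), image_w, image_h)
    # a box refined out of the image stays dead; park it on a unit box so
    # later pooling passes remain well-defined
    dead <- dead | cl$degenerate
    cl$xmax[cl$degenerate] <- cl$xmin[cl$degenerate] + 1
    cl$ymax[cl$degenerate] <- cl$ymin[cl$degenerate] + 1
    boxes <- clip_boxes(cl[, 1:4], image_w, image_h)[, 1:4]
    boxes$xmax <- pmax(boxes$xmax, boxes$xmin + 1e-3)
    boxes$ymax <- pmax(boxes$ymax, boxes$ymin + 1e-3)
  }
  long_side <- pmax(boxes$xmax - boxes$xmin, boxes$ymax - boxes$ymin)
  degenerate <- dead | long_side < min(model$anchors$scales)
  ok_idx <- which(!degenerate)
  probs <- matrix(0, nrow(props), C + 1L)
  probs[, C + 1L] <- 1
  if (length(ok_idx)) {
    rois2 <- box_to_feature_roi(boxes[ok_idx, ], model$anchors$stride, W, H)
    ps2 <- ps_heads_forward(head_out$cls_maps, head_out$reg_maps, rois2,
                            model$pspm_k, C)
    probs[ok_idx, ] <- softmax_rows(ps2$r)
  }
  dets <- purrr::map_dfr(seq_len(C), function(ci) {
    keep <- which(probs[, ci] >= score_thresh & !degenerate)
    if (!length(keep)) return(NULL)
    tibble(image_id = id, label = model$classes[ci], score = probs[keep, ci],
           xmin = boxes$xmin[keep], ymin = boxes$ymin[keep],
           xmax = boxes$xmax[keep], ymax = boxes$ymax[keep])
  })
  if (nrow(dets) == 0L) return(empty)
  out <- suppress_per_class(dets, suppression)
  out <- out[out$score >= score_thresh, , drop = FALSE]
  out <- out[order(out$score, decreasing = TRUE), , drop = FALSE]
  out[, c("image_id", "label", "score", "xmin", "ymin", "xmax", "ymax")]
}

#' Save / load a trained detector
#'
#' The whole model object -- parameters plus the anchor, suppression and
#' head configuration captured at training time -- is serialized, so
#' inference after a reload is bit-identical.
#'
#' @param model A `grain_detector`.
#' @param path File path.
#' @return `path` (save) or the reloaded `grain_detector` (load).
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "grain_detector"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "grain_detector"))
  model
}
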