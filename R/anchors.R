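# Anchor generation on a strided feature grid, and anchor-to-ground-truth
# matching with the standard positive/negative/ignore labeling.

#' Anchor configuration
#'
#' Scales are side lengths in input-image pixels (an anchor for scale s has
#' area s^2); ratios are height:width, with width = s / sqrt(r) and
#' height = s * sqrt(r) so the area is preserved exactly. The default is the
#' enhanced five-scale set tuned to 8-48 px insect bodies; the classical
#' baseline uses `scales = c(8, 16, 32)` (k = 9).
#'
#' @param scales Strictly increasing positive side lengths, pixels.
#' @param ratios Aspect ratios (height:width).
#' @param stride Feature-map subsampling factor, pixels.
#' @return An `anchor_config` list with element `k = length(scales) * length(ratios)`.
#' @export
anchor_config <- function(scales = c(8, 16, 24, 32, 48),
                          ratios = c(1, 0.5, 2),
                          stride = 16) {
  if (length(scales) == 0 || length(ratios) == 0) {
    abort("anchor config error: scales and ratios must be non-empty")
  }
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE)) {
    abort("anchor config error: scales must be strictly positive and increasing")
  }
  structure(
    list(scales = scales, ratios = ratios, stride = stride,
         k = length(scales) * length(ratios)),
    class = "anchor_config"
  )
}

# the k per-cell anchor shapes, centered at origin: ratio-major, scale-minor
anchor_shapes <- function(config) {
  grid <- expand.grid(scale = config$scales, ratio = config$ratios)
  w <- grid$scale / sqrt(grid$ratio)
  h <- grid$scale * sqrt(grid$ratio)
  cbind(-w / 2, -h / 2, w / 2, h / 2)
}

#' Generate anchors over a feature grid
#'
#' Produces `feat_w * feat_h * k` anchors, k per grid cell, centered at
#' `((x + 0.5) * stride, (y + 0.5) * stride)` for cell (x, y) (0-based). In
#' `"train"` mode anchors crossing the image boundary are flagged invalid and
#' are excluded from loss computation; in `"test"` mode all anchors are valid
#' and downstream boxes are clipped instead.
#'
#' Anchor order: cells row-major (y outer, x inner), the k shapes innermost
#' (ratio-major, scale-minor).
#'
#' @param config An [anchor_config()].
#' @param feat_w,feat_h Feature-map dimensions.
#' @param image_w,image_h Input-image dimensions, pixels.
#' @param mode `"train"` or `"test"`.
#' @return List with `anchors` (tibble xmin..ymax) and `valid` (logical).
#' @export
generate_anchors <- function(config, feat_w, feat_h, image_w, image_h,
                             mode = c("train", "test")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "anchor_config"), feat_w >= 1, feat_h >= 1)
  shapes <- anchor_shapes(config)
  k <- config$k
  cx <- (rep(seq_len(feat_w) - 1, times = feat_h) + 0.5) * config$stride
  cy <- (rep(seq_len(feat_h) - 1, each = feat_w) + 0.5) * config$stride
  n_cell <- feat_w * feat_h
  centers <- cbind(cx, cy, cx, cy)
  anchors <- centers[rep(seq_len(n_cell), each = k), , drop = FALSE] +
    shapes[rep(seq_len(k), times = n_cell), , drop = FALSE]
  valid <- if (mode == "train") {
    anchors[, 1] >= 0 & anchors[, 2] >= 0 &
      anchors[, 3] <= image_w & anchors[, 4] <= image_h
  } else {
    rep(TRUE, nrow(anchors))
  }
  list(
    anchors = tibble(xmin = unname(anchors[, 1]), ymin = unname(anchors[, 2]),
                     xmax = unname(anchors[, 3]), ymax = unname(anchors[, 4])),
    valid = unname(valid)
  )
}

#' Label anchors against ground-truth boxes
#'
#' An anchor is positive if (i) it attains the maximum IoU for some ground
#' truth (among valid anchors, with a nonzero overlap), or (ii) its IoU with
#' any ground truth exceeds `pos_iou`. It is negative if valid and its best
#' IoU is below `neg_iou`. Everything else -- including all invalid anchors --
#' is ignored. Ties in the per-ground-truth argmax are broken by the lowest
#' anchor index; an anchor matched to several ground truths takes the one of
#' highest IoU, ties broken by lowest ground-truth index.
#'
#' @param anchors Anchor box table.
#' @param valid Logical validity mask (from [generate_anchors()]).
#' @param gts Ground-truth box table (difficult annotations must already be
#'   excluded).
#' @param pos_iou,neg_iou Positive/negative IoU thresholds (defaults 0.7/0.3).
#' @return List with `labels` (factor positive/negative/ignore),
#'   `matched_gt` (index of matched ground truth, NA unless positive) and
#'   `max_iou` (per-anchor best IoU).
#' @export
match_anchors <- function(anchors, valid, gts, pos_iou = 0.7, neg_iou = 0.3) {
  if (pos_iou <= neg_iou) {
    abort("anchor matching config error: pos_iou must exceed neg_iou")
  }
  a <- box_matrix(anchors)
  n <- nrow(a)
  stopifnot(length(valid) == n)
  g <- if (is.null(gts) || NROW(gts) == 0L) {
    matrix(numeric(0), 0, 4)
  } else {
    box_matrix(gts)
  }
  labels <- rep("ignore", n)
  matched <- rep(NA_integer_, n)
  if (nrow(g) == 0L) {
    labels[valid] <- "negative"
    return(list(labels = factor(labels, c("positive", "negative", "ignore")),
                matched_gt = matched, max_iou = rep(0, n)))
  }
  M <- iou_matrix(a, g)
  best_gt <- max.col(M, ties.method = "first") # lowest gt index on ties
  max_iou <- M[cbind(seq_len(n), best_gt)]
  labels[valid & max_iou < neg_iou] <- "negative"
  pos <- valid & max_iou > pos_iou
  # rule (i): the argmax anchor for each gt, among valid anchors with IoU > 0
  Mv <- M
  Mv[!valid, ] <- -1
  for (j in seq_len(ncol(M))) {
    m <- max(Mv[, j])
    if (m > 0) pos[which(Mv[, j] == m)[1]] <- TRUE # lowest anchor index
  }
  labels[pos] <- "positive"
  matched[pos] <- best_gt[pos]
  list(labels = factor(labels, c("positive", "negative", "ignore")),
       matched_gt = matched, max_iou = max_iou)
}
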