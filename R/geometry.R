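# Axis-aligned boxes are kept in 0-based, half-open pixel coordinates
# [xmin, xmax) x [ymin, ymax), origin at the image's top-left corner, so that
# width = xmax - xmin exactly. Tabular interfaces use tibbles with columns
# xmin, ymin, xmax, ymax; hot inner loops use plain 4-column matrices.

box_matrix <- function(boxes) {
  if (is.matrix(boxes)) {
    stopifnot(ncol(boxes) == 4L)
    return(unname(boxes))
  }
  if (is.data.frame(boxes)) {
    return(unname(as.matrix(boxes[, c("xmin", "ymin", "xmax", "ymax")])))
  }
  if (is.numeric(boxes) && length(boxes) == 4L) {
    return(matrix(unname(boxes), nrow = 1L))
  }
  abort("boxes must be a 4-column matrix/data frame or a length-4 numeric")
}

assert_valid_boxes <- function(b, what = "box") {
  if (!all(is.finite(b))) abort(paste0(what, " coordinates must be finite"))
  if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2])) {
    abort(paste0(what, " must satisfy xmax > xmin and ymax > ymin"))
  }
  invisible(b)
}

box_width <- function(b) b[, 3] - b[, 1]
box_height <- function(b) b[, 4] - b[, 2]

#' Box areas
#'
#' @param boxes A tibble/matrix of boxes with columns xmin, ymin, xmax, ymax
#'   in half-open pixel coordinates.
#' @return Numeric vector of areas (pixels squared).
#' @export
box_area <- function(boxes) {
  b <- box_matrix(boxes)
  pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
}

#' Intersection over union of two boxes
#'
#' The Jaccard overlap of two axis-aligned boxes: intersection area divided by
#' union area. Equals 1 for identical boxes, 0 for disjoint ones, and is
#' invariant to a common rescaling of both boxes.
#'
#' @param p,g Single boxes (length-4 numeric, 1-row matrix, or 1-row data
#'   frame) with coordinates xmin, ymin, xmax, ymax.
#' @return A number in \[0, 1\].
#' @examples
#' iou(c(0, 0, 10, 10), c(0, 5, 10, 15)) # 1/3
#' @export
iou <- function(p, g) {
  pm <- box_matrix(p)
  gm <- box_matrix(g)
  if (any(box_area(pm) <= 0) || any(box_area(gm) <= 0)) {
    abort("iou() requires boxes with positive area")
  }
  drop(iou_matrix(pm, gm))
}

#' Pairwise IoU matrix
#'
#' @param a,b Box tables (n x 4 and m x 4).
#' @return An n x m matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- box_matrix(a)
  b <- box_matrix(b)
  n <- nrow(a)
  m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  ix1 <- outer(a[, 1], b[, 1], pmax)
  iy1 <- outer(a[, 2], b[, 2], pmax)
  ix2 <- outer(a[, 3], b[, 3], pmin)
  iy2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(0, ix2 - ix1) * pmax(0, iy2 - iy1)
  union <- outer(box_area(a), box_area(b), `+`) - inter
  out <- inter / union
  out[union <= 0] <- 0
  out
}

#' Clip boxes to image bounds
#'
#' Coordinates are clamped to \[0, width\] x \[0, height\]. Boxes left with zero
#' area are flagged `degenerate` rather than dropped, so callers can decide.
#'
#' @param boxes Box tibble or matrix.
#' @param image_w,image_h Image dimensions in pixels.
#' @return A tibble with columns xmin, ymin, xmax, ymax, degenerate.
#' @export
clip_boxes <- function(boxes, image_w, image_h) {
  b <- box_matrix(boxes)
  out <- cbind(
    pmin(pmax(b[, 1], 0), image_w),
    pmin(pmax(b[, 2], 0), image_h),
    pmin(pmax(b[, 3], 0), image_w),
    pmin(pmax(b[, 4], 0), image_h)
  )
  tibble(
    xmin = out[, 1], ymin = out[, 2], xmax = out[, 3], ymax = out[, 4],
    degenerate = (out[, 3] - out[, 1]) <= 0 | (out[, 4] - out[, 2]) <= 0
  )
}

#' Encode boxes as regression deltas relative to anchors
#'
#' The standard center/log-size parameterization: tx = (gx - ax) / aw,
#' ty = (gy - ay) / ah, tw = log(gw / aw), th = log(gh / ah), where (gx, gy)
#' and (ax, ay) are box and anchor centers and (gw, gh), (aw, ah) their sizes.
#'
#' @param gt,anchors Box tables of equal row count (or one of them 1-row).
#' @return A tibble with columns tx, ty, tw, th.
#' @export
encode_boxes <- function(gt, anchors) {
  g <- box_matrix(gt)
  a <- box_matrix(anchors)
  if (nrow(g) == 1L && nrow(a) > 1L) g <- g[rep(1L, nrow(a)), , drop = FALSE]
  if (nrow(a) == 1L && nrow(g) > 1L) a <- a[rep(1L, nrow(g)), , drop = FALSE]
  assert_valid_boxes(g, "ground-truth box")
  assert_valid_boxes(a, "anchor box")
  gw <- box_width(g); gh <- box_height(g)
  aw <- box_width(a); ah <- box_height(a)
  gx <- g[, 1] + gw / 2; gy <- g[, 2] + gh / 2
  ax <- a[, 1] + aw / 2; ay <- a[, 2] + ah / 2
  tibble(
    tx = (gx - ax) / aw,
    ty = (gy - ay) / ah,
    tw = log(gw / aw),
    th = log(gh / ah)
  )
}

#' Decode regression deltas onto anchors
#'
#' Exact inverse of [encode_boxes()].
#'
#' @param deltas Delta table with columns tx, ty, tw, th (or n x 4 matrix).
#' @param anchors Anchor box table, one row per delta row.
#' @return A tibble of boxes with columns xmin, ymin, xmax, ymax.
#' @export
decode_boxes <- function(deltas, anchors) {
  d <- if (is.data.frame(deltas)) {
    unname(as.matrix(deltas[, c("tx", "ty", "tw", "th")]))
  } else if (is.numeric(deltas) && !is.matrix(deltas)) {
    matrix(deltas, ncol = 4L)
  } else {
    unname(as.matrix(deltas))
  }
  a <- box_matrix(anchors)
  if (nrow(a) == 1L && nrow(d) > 1L) a <- a[rep(1L, nrow(d)), , drop = FALSE]
  assert_valid_boxes(a, "anchor box")
  aw <- box_width(a); ah <- box_height(a)
  ax <- a[, 1] + aw / 2; ay <- a[, 2] + ah / 2
  gx <- d[, 1] * aw + ax
  gy <- d[, 2] * ah + ay
  gw <- exp(d[, 3]) * aw
  gh <- exp(d[, 4]) * ah
  tibble(
    xmin = gx - gw / 2, ymin = gy - gh / 2,
    xmax = gx + gw / 2, ymax = gy + gh / 2
  )
}
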