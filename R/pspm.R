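# Position-sensitive RoI pooling. The classification head emits k^2 * (C+1)
# score maps: one map per (bin, class) pair, where the k x k bins encode
# relative position within the object ("top-left of the insect", ...). An
# RoI is split into k x k bins and bin (i, j) for class c average-pools ONLY
# its dedicated channel over that bin's cells; the k^2 bin responses are then
# averaged (voting) and softmaxed across classes. Regression uses the same
# pooling over 4 k^2 class-agnostic maps. Nothing after the RoI stage has
# trainable parameters.
#
# Channel layout (1-based): channel = group * k^2 + j * k + i + 1, with
# i the 0-based x-bin, j the 0-based y-bin, and group the 0-based class
# index (classification maps; foreground classes first, background last) or
# the 0-based coordinate index tx, ty, tw, th (regression maps).

ps_channel <- function(group0, i, j, k) group0 * k^2 + j * k + i + 1

bin_cells <- function(offset, extent, i, k) {
  # 0-based cell range floor(i*extent/k) <= t < ceil((i+1)*extent/k)
  lo <- floor(i * extent / k)
  hi <- ceiling((i + 1) * extent / k) - 1
  if (hi < lo) return(integer(0))
  (offset + lo):(offset + hi) + 1L # 1-based array indices
}

check_roi <- function(roi, map_h, map_w) {
  roi <- as.numeric(roi)
  stopifnot(length(roi) == 4L)
  if (roi[3] < 1 || roi[4] < 1) abort("RoI width and height must be >= 1")
  if (roi[1] < 0 || roi[2] < 0 ||
      roi[1] + roi[3] > map_w || roi[2] + roi[4] > map_h) {
    abort("RoI lies outside the feature map")
  }
  roi
}

#' Position-sensitive RoI pooling of classification score maps
#'
#' @param maps Numeric array `H x W x (k^2 * (C+1))` of score maps.
#' @param roi RoI rectangle `c(x0, y0, w, h)` in 0-based feature-map cells.
#' @param k Bin grid size (default 3).
#' @param C Number of foreground classes.
#' @return Array `k x k x (C+1)`; entry `[i, j, c]` is the average of channel
#'   (i, j, c) over bin (i, j)'s cells (0 for empty bins).
#' @export
ps_roi_pool <- function(maps, roi, k = 3, C) {
  stopifnot(length(dim(maps)) == 3L, dim(maps)[3] == k^2 * (C + 1))
  roi <- check_roi(roi, dim(maps)[1], dim(maps)[2])
  out <- array(0, c(k, k, C + 1))
  for (j in 0:(k - 1)) {
    rows <- bin_cells(roi[2], roi[4], j, k)
    for (i in 0:(k - 1)) {
      cols <- bin_cells(roi[1], roi[3], i, k)
      if (length(rows) == 0L || length(cols) == 0L) next
      for (c0 in 0:C) {
        ch <- ps_channel(c0, i, j, k)
        out[i + 1, j + 1, c0 + 1] <- mean(maps[rows, cols, ch])
      }
    }
  }
  out
}

#' Vote bin scores into class probabilities
#'
#' Averages the k^2 position-sensitive bin responses per class and applies a
#' softmax across the C+1 classes. Parameter-free.
#'
#' @param bin_table Output of [ps_roi_pool()] (`k x k x (C+1)` array).
#' @return Probability vector of length C+1 summing to 1.
#' @export
vote_scores <- function(bin_table) {
  r <- apply(bin_table, 3, mean)
  e <- exp(r - max(r))
  e / sum(e)
}

#' Position-sensitive pooling of the class-agnostic regression maps
#'
#' @param maps Numeric array `H x W x 4k^2` of regression maps.
#' @param roi RoI rectangle `c(x0, y0, w, h)` in 0-based feature-map cells.
#' @param k Bin grid size.
#' @return Named delta vector `c(tx, ty, tw, th)` (per-bin pooled values
#'   averaged over the k^2 bins; empty bins contribute 0).
#' @export
pool_regression <- function(maps, roi, k = 3) {
  stopifnot(length(dim(maps)) == 3L, dim(maps)[3] == 4 * k^2)
  roi <- check_roi(roi, dim(maps)[1], dim(maps)[2])
  out <- numeric(4)
  for (coord in 0:3) {
    acc <- 0
    for (j in 0:(k - 1)) {
      rows <- bin_cells(roi[2], roi[4], j, k)
      for (i in 0:(k - 1)) {
        cols <- bin_cells(roi[1], roi[3], i, k)
        if (length(rows) == 0L || length(cols) == 0L) next
        acc <- acc + mean(maps[rows, cols, ps_channel(coord, i, j, k)])
      }
    }
    out[coord + 1] <- acc / k^2
  }
  setNames(out, c("tx", "ty", "tw", "th"))
}

# ---- batched forward/backward used by the training loop --------------------
# Forward returns the pre-softmax voted responses r (n_roi x (C+1)) and the
# pooled deltas (n_roi x 4); backward scatters gradients w.r.t. those
# outputs back into dense map gradients. Average pooling + voting is linear,
# so each cell of bin (i, j) receives grad / (k^2 * n_cells).

ps_heads_forward <- function(cls_maps, reg_maps, rois, k, C) {
  n <- nrow(rois)
  r <- matrix(0, n, C + 1)
  t <- matrix(0, n, 4)
  for (q in seq_len(n)) {
    bt <- ps_roi_pool(cls_maps, rois[q, ], k, C)
    r[q, ] <- apply(bt, 3, mean)
    t[q, ] <- pool_regression(reg_maps, rois[q, ], k)
  }
  list(r = r, t = t)
}

ps_heads_backward <- function(dim_cls, dim_reg, rois, k, C, dr, dt) {
  d_cls <- array(0, dim_cls)
  d_reg <- array(0, dim_reg)
  for (q in seq_len(nrow(rois))) {
    roi <- as.numeric(rois[q, ])
    for (j in 0:(k - 1)) {
      rows <- bin_cells(roi[2], roi[4], j, k)
      for (i in 0:(k - 1)) {
        cols <- bin_cells(roi[1], roi[3], i, k)
        ncell <- length(rows) * length(cols)
        if (ncell == 0L) next
        for (c0 in 0:C) {
          g <- dr[q, c0 + 1] / (k^2 * ncell)
          if (g != 0) {
            ch <- ps_channel(c0, i, j, k)
            d_cls[rows, cols, ch] <- d_cls[rows, cols, ch] + g
          }
        }
        for (coord in 0:3) {
          g <- dt[q, coord + 1] / (k^2 * ncell)
          if (g != 0) {
            ch <- ps_channel(coord, i, j, k)
            d_reg[rows, cols, ch] <- d_reg[rows, cols, ch] + g
          }
        }
      }
    }
  }
  list(d_cls = d_cls, d_reg = d_reg)
}
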