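# Independent reference implementations used as oracles. These are literal,
# slow transcriptions kept deliberately separate from the package's code
# paths.

iou_scalar <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (b[3] - b[1]) * (b[4] - b[2])
  unname(if (aa + ab - inter <= 0) 0 else inter / (aa + ab - inter))
}

# step-by-step transcription of the score-decay pruning rules:
# linear: s_i <- s_i            if iou(M, b_i) <  Nt
#         s_i <- s_i (1 - iou)  if iou(M, b_i) >= Nt
# gaussian: s_i <- s_i * exp(-iou(M, b_i)^2 / sigma) for every b_i not in D
oracle_soft_nms <- function(boxes, scores, mode, Nt = 0.3, sigma = 0.5,
                            floor = 0.001) {
  B <- lapply(seq_len(nrow(boxes)), function(i) boxes[i, ])
  S <- scores
  idx <- seq_along(S)
  D <- list()
  while (length(B) > 0) {
    m <- 1
    for (i in seq_along(S)) if (S[i] > S[m]) m <- i
    D[[length(D) + 1]] <- list(box = B[[m]], score = S[m], index = idx[m])
    M <- B[[m]]
    B <- B[-m]; S <- S[-m]; idx <- idx[-m]
    if (length(B) == 0) break
    for (i in seq_along(B)) {
      ov <- iou_scalar(M, B[[i]])
      if (mode == "linear") {
        if (ov >= Nt) S[i] <- S[i] * (1 - ov)
      } else {
        S[i] <- S[i] * exp(-ov^2 / sigma)
      }
    }
    keep <- S >= floor
    B <- B[keep]; S <- S[keep]; idx <- idx[keep]
  }
  data.frame(
    index = vapply(D, function(d) d$index, 0),
    score = vapply(D, function(d) d$score, 0)
  )
}

oracle_hard_nms <- function(boxes, scores, Nt = 0.3) {
  B <- lapply(seq_len(nrow(boxes)), function(i) boxes[i, ])
  S <- scores
  idx <- seq_along(S)
  D <- integer(0)
  while (length(B) > 0) {
    m <- 1
    for (i in seq_along(S)) if (S[i] > S[m]) m <- i
    D <- c(D, idx[m])
    M <- B[[m]]
    B <- B[-m]; S <- S[-m]; idx <- idx[-m]
    if (length(B) == 0) break
    keep <- vapply(B, function(b) iou_scalar(M, b) <= Nt, TRUE)
    B <- B[keep]; S <- S[keep]; idx <- idx[keep]
  }
  D
}

# literal triple-loop evaluation of the per-bin average-pooling rule:
# r_c(i, j) = sum_{(x, y) in bin(i, j)} z_{i, j, c}(x + x0, y + y0) / n
oracle_ps_pool <- function(maps, roi, k, C) {
  x0 <- roi[1]; y0 <- roi[2]; w <- roi[3]; h <- roi[4]
  out <- array(0, c(k, k, C + 1))
  for (c0 in 0:C) {
    for (j in 0:(k - 1)) {
      for (i in 0:(k - 1)) {
        xs <- floor(i * w / k):(ceiling((i + 1) * w / k) - 1)
        ys <- floor(j * h / k):(ceiling((j + 1) * h / k) - 1)
        xs <- xs[xs >= floor(i * w / k)]
        acc <- 0; n <- 0
        for (y in ys) {
          for (x in xs) {
            if (x < 0 || y < 0 || x >= w || y >= h) next
            ch <- c0 * k^2 + j * k + i + 1
            acc <- acc + maps[y0 + y + 1, x0 + x + 1, ch]
            n <- n + 1
          }
        }
        out[i + 1, j + 1, c0 + 1] <- if (n > 0) acc / n else 0
      }
    }
  }
  out
}

oracle_pool_regression <- function(maps, roi, k) {
  out <- numeric(4)
  for (coord in 0:3) {
    sub <- maps[, , coord * k^2 + seq_len(k^2), drop = FALSE]
    bt <- oracle_ps_pool(sub, roi, k, 0) # one "class" = this coordinate
    out[coord + 1] <- mean(bt)
  }
  out
}

# transform a box by rasterizing it, transforming the pixel mask, and taking
# tight bounds of the transformed mask
oracle_augmented_box <- function(box, width, height, op) {
  m <- array(0, c(height, width, 3))
  m[(floor(box[2]) + 1):ceiling(box[4]),
    (floor(box[1]) + 1):ceiling(box[3]), ] <- 1
  t <- augment_record(image_record("mask", m), op)
  w <- which(t$pixels[, , 1] > 0, arr.ind = TRUE)
  c(min(w[, 2]) - 1, min(w[, 1]) - 1, max(w[, 2]), max(w[, 1]))
}

# exhaustive optimal one-to-one assignment of detections to ground truths
# (used only for <= 3 boxes): maximizes TP count at the IoU threshold
oracle_best_assignment_tp <- function(dets, gts, thresh) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0 || ng == 0) return(0L)
  ok <- matrix(FALSE, nd, ng)
  for (d in seq_len(nd)) {
    for (g in seq_len(ng)) {
      ok[d, g] <- iou_scalar(
        as.numeric(dets[d, c("xmin", "ymin", "xmax", "ymax")]),
        as.numeric(gts[g, c("xmin", "ymin", "xmax", "ymax")])) >= thresh
    }
  }
  # exhaustive search over injective det -> gt assignments
  recurse <- function(d, free) {
    if (d > nd) return(0L)
    best <- recurse(d + 1L, free) # leave det d unmatched
    for (g in which(free)) {
      if (ok[d, g]) {
        f2 <- free; f2[g] <- FALSE
        best <- max(best, 1L + recurse(d + 1L, f2))
      }
    }
    best
  }
  recurse(1L, rep(TRUE, ng))
}

# small random scene fixtures used across test files
tiny_scene_config <- function(count_range = c(2, 5), ...) {
  scene_config(width = 120, height = 120, count_range = count_range,
               size_range = c(10, 26), difficult_prob = 0, ...)
}

random_boxes <- function(n, extent = 100, min_side = 4, max_side = 25) {
  x <- runif(n, 0, extent - max_side)
  y <- runif(n, 0, extent - max_side)
  w <- runif(n, min_side, max_side)
  h <- runif(n, min_side, max_side)
  tibble::tibble(xmin = x, ymin = y, xmax = x + w, ymax = y + h)
}
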